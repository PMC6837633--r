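# parse one flat "key: value" (or "key = value") file into a named list;
# values are converted to logical/numeric where unambiguous
parse_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regexpr("[:=]", ln)
    if (m < 0) stop("malformed config line (expected 'key: value'): ", ln)
    key <- trimws(substr(ln, 1, m - 1))
    val <- trimws(substr(ln, m + 1, nchar(ln)))
    if (!nzchar(key)) stop("malformed config line: ", ln)
    out[[key]] <-
      if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else if (grepl("^[-+]?([0-9]*\\.)?[0-9]+([eE][-+]?[0-9]+)?$", val))
        as.numeric(val)
      else val
  }
  out
}

#' Load and validate a run configuration file
#'
#' Reads a flat key-value configuration file (one `key: value` per line;
#' `#` starts a comment), rejects unknown keys, fills defaults (see
#' [evolution_config()]) and validates every field against its allowed
#' range.
#'
#' @param path Path to the configuration file.
#' @return An [evolution_config()] object.
#' @examples
#' p <- tempfile(fileext = ".yml")
#' writeLines(c("N: 100", "nu: 0.1", "seed: 1"), p)
#' load_config(p)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- parse_flat_config(path)
  known <- names(formals(evolution_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; allowed keys: ", paste(known, collapse = ", "))
  do.call(evolution_config, raw)
}

#' Write a run configuration file
#'
#' @param cfg An [evolution_config()] (or named list of fields).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  if (inherits(cfg, "evo_config")) cfg <- unclass(cfg)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  vals <- vapply(cfg, function(v) {
    if (is.logical(v)) tolower(as.character(v)) else format(v, digits = 15)
  }, character(1))
  writeLines(paste0(names(cfg), ": ", vals), path)
  invisible(path)
}

#' Generate canned configuration fixtures
#'
#' Emits small, reduced-scale configuration files for the named study
#' setups: `fig3_small.yml` (non-optimal monostable founder
#' `k = 80, n_H = 1, K_D = 10` under fast fluctuations), its deterministic
#' twin `control_twin.yml`, `theta1_small.yml` (founder
#' `k = 80, n_H = 6, K_D = 45`, closer to the finally selected genotypes),
#' and `map_grid.yml` (the analysis grid for the potential / noise-load
#' maps). All fixtures round-trip through [load_config()].
#'
#' @param out_dir Writable output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fig3 <- list(N = 500L, nu = 0.1, st = 40L, u = 0.03, M = 1.1,
               generations = 2000L, k0 = 80, nH0 = 1, KD0 = 10, seed = 1L)
  ctrl <- c(fig3, list(control = TRUE))
  theta1 <- list(N = 500L, nu = 0.1, st = 40L, u = 0.03, M = 1.1,
                 generations = 2000L, k0 = 80, nH0 = 6, KD0 = 45, seed = 1L)
  paths <- c(fig3 = file.path(out_dir, "fig3_small.yml"),
             control_twin = file.path(out_dir, "control_twin.yml"),
             theta1 = file.path(out_dir, "theta1_small.yml"),
             map_grid = file.path(out_dir, "map_grid.yml"))
  write_config(fig3, paths[["fig3"]])
  write_config(ctrl, paths[["control_twin"]])
  write_config(theta1, paths[["theta1"]])
  grid <- map_grid()
  writeLines(c(paste0("n_nH: ", length(grid$n_H)),
               paste0("n_KD: ", length(grid$K_D)),
               "nH_min: 1", "nH_max: 16", "KD_min: 1", "KD_max: 120",
               "M: 1.1", "tau: 4"),
             paths[["map_grid"]])
  invisible(paths)
}
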