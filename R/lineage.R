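# Walk ancestral paths through the archive rows and collect, per traced
# cell: the ancestor index at `to_gen`, the number of mutations on the
# way, and whether every genotype on the window was bistable. `rows[[g+1]]`
# holds the population of generation g; `idx` indexes row `from_gen`.
trace_window <- function(rows, bist, from_gen, to_gen, idx) {
  if (from_gen <= to_gen) stop("window must span at least one generation")
  nmut <- integer(length(idx))
  allb <- bist[rows[[from_gen + 1L]]$gid[idx]]
  g <- from_gen
  while (g > to_gen) {
    row <- rows[[g + 1L]]
    if (is.null(row)) stop("archive does not cover the requested window")
    nmut <- nmut + row$mutated[idx]
    idx <- row$parent[idx]
    g <- g - 1L
    allb <- allb & bist[rows[[g + 1L]]$gid[idx]]
  }
  list(idx = idx, nmut = nmut, allbist = allb)
}

# strategy label from window summaries (vectorized)
label_strategy <- function(allbist, nmut) {
  ifelse(allbist & nmut == 0L, "ES",
         ifelse(allbist, "BA",
                ifelse(nmut > 0L, "GA", "STATIC")))
}

# classification windows for the population alive at generation e_now:
# current strategy = window (e2, e1] (between the 2-cycle and 1-cycle
# ancestors); previous strategy = window (e3, e2] when e3 is available
lineage_stats <- function(rows, bist, e_now, e1, e2, e3 = NA_integer_) {
  N <- length(rows[[e_now + 1L]]$gid)
  idx <- seq_len(N)
  # hop from the current population back to its 1-cycle ancestors
  g <- e_now
  while (g > e1) {
    idx <- rows[[g + 1L]]$parent[idx]
    g <- g - 1L
  }
  cur <- trace_window(rows, bist, from_gen = e1, to_gen = e2, idx = idx)
  out <- list(current = label_strategy(cur$allbist, cur$nmut))
  if (!is.na(e3)) {
    prev <- trace_window(rows, bist, from_gen = e2, to_gen = e3,
                         idx = cur$idx)
    out$previous <- label_strategy(prev$allbist, prev$nmut)
  }
  out
}

#' Classify the adaptation strategy of one ancestral path
#'
#' Given the genotype states along a lineage's path over one full
#' environmental cycle (from its 2-cycle ancestor to its 1-cycle ancestor)
#' and the mutation events on that path, the strategy is: **ES**
#' (epigenetic switching) if every genotype on the window is bistable and
#' no mutation occurred; **BA** (bistable adaptation) if every genotype is
#' bistable and at least one mutation occurred; **GA** (genetic
#' adaptation) if any genotype is monostable and mutations accumulated;
#' **STATIC** otherwise (a monostable path with no mutations, which
#' matches none of the three named strategies and is reported as a fourth
#' category).
#'
#' @param bistable Logical vector: bistability of the genotype at each
#'   generation along the window (length `L + 1` for a window of `L`
#'   generations).
#' @param mutated Logical (or 0/1) vector of per-generation mutation
#'   events along the window (length `L`).
#' @param cycle_length If given, the window must cover at least one full
#'   cycle (`L >= cycle_length`), otherwise an error is raised.
#' @return One of `"ES"`, `"BA"`, `"GA"`, `"STATIC"`.
#' @export
classify_strategy <- function(bistable, mutated, cycle_length = NULL) {
  if (length(bistable) != length(mutated) + 1L)
    stop("bistable must have one more element than mutated")
  if (!is.null(cycle_length) && length(mutated) < cycle_length)
    stop("window shorter than one environmental cycle")
  label_strategy(all(bistable), sum(mutated))
}

#' Strategy fractions of the surviving population at a cycle end
#'
#' Every cell alive at the end of cycle `cycle` contributes the strategy
#' label of its ancestral window between its 2-cycle and 1-cycle
#' ancestors; each individual ancestral lineage is counted regardless of
#' whether it is shared, so the fractions are progeny-weighted.
#'
#' @param archive A `"lineage_archive"` (from
#'   `run_evolution(..., keep_archive = TRUE)`).
#' @param cycle Cycle index (must leave at least two complete cycles of
#'   history before it).
#' @return Named numeric vector of fractions over
#'   `c("ES", "BA", "GA", "STATIC")`, summing to 1.
#' @export
strategy_fractions <- function(archive, cycle) {
  stopifnot(inherits(archive, "lineage_archive"))
  ends0 <- c(0L, archive$cycle_ends)
  if (cycle < 2L || cycle + 1L > length(ends0))
    stop("archive must cover at least two full cycles before this cycle")
  st <- lineage_stats(archive$rows, archive$bistable,
                      e_now = ends0[cycle + 1L], e1 = ends0[cycle],
                      e2 = ends0[cycle - 1L])
  fr <- prop.table(table(factor(st$current,
                                levels = c("ES", "BA", "GA", "STATIC"))))
  stats::setNames(as.numeric(fr), names(fr))
}

#' Transition statistics between adaptation strategies
#'
#' For the population surviving at the end of `cycle`, compares the
#' strategy of the window between the 2-cycle and 1-cycle ancestors
#' (current strategy) against the window between the 3-cycle and 2-cycle
#' ancestors (previous strategy), progeny-weighted, and normalizes each
#' row of the resulting (previous -> current) contingency table.
#'
#' @inheritParams strategy_fractions
#' @return 4 x 4 row-stochastic matrix over
#'   `c("ES", "BA", "GA", "STATIC")` (rows with no mass are left at 0).
#' @export
transition_statistics <- function(archive, cycle) {
  stopifnot(inherits(archive, "lineage_archive"))
  ends0 <- c(0L, archive$cycle_ends)
  if (cycle < 3L || cycle + 1L > length(ends0))
    stop("archive must cover at least three full cycles before this cycle")
  st <- lineage_stats(archive$rows, archive$bistable,
                      e_now = ends0[cycle + 1L], e1 = ends0[cycle],
                      e2 = ends0[cycle - 1L], e3 = ends0[cycle - 2L])
  levs <- c("ES", "BA", "GA", "STATIC")
  tab <- unclass(table(factor(st$previous, levels = levs),
                       factor(st$current, levels = levs)))
  rs <- rowSums(tab)
  sweep(tab, 1, ifelse(rs > 0, rs, 1), "/")
}

#' Write run outputs as delimited tables
#'
#' Writes `generations.csv`, `cycles.csv`, `lineages.csv` and, when
#' transition statistics were computed, `transitions.csv` into a
#' directory.
#'
#' @param run An `"evo_run"` result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "evo_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "generations.csv"), file.path(dir, "cycles.csv"),
             file.path(dir, "lineages.csv"))
  utils::write.csv(run$generations, paths[1], row.names = FALSE)
  utils::write.csv(run$cycles, paths[2], row.names = FALSE)
  utils::write.csv(run$lineages, paths[3], row.names = FALSE)
  if (!is.null(run$transitions)) {
    p <- file.path(dir, "transitions.csv")
    utils::write.csv(as.data.frame(run$transitions), p, row.names = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
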