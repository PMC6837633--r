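# genotype registry: append-only store of every genotype seen in a run,
# with cached stability information (bistability is a property of the
# genotype, so it is computed once per genotype, not per cell). Backed by
# an environment with doubling preallocation so lookups never copy.
new_registry <- function(alpha, gamma, init_capacity = 1024L) {
  reg <- new.env(parent = emptyenv())
  reg$alpha <- alpha
  reg$gamma <- gamma
  reg$cap <- init_capacity
  reg$n <- 0L
  reg$k <- numeric(init_capacity)
  reg$nH <- numeric(init_capacity)
  reg$KD <- numeric(init_capacity)
  reg$bist <- logical(init_capacity)
  reg$basins <- vector("list", init_capacity)
  reg
}

reg_register <- function(reg, k1, n1, K1) {
  if (reg$n + 1L > reg$cap) {
    reg$cap <- reg$cap * 2L
    length(reg$k) <- reg$cap
    length(reg$nH) <- reg$cap
    length(reg$KD) <- reg$cap
    length(reg$bist) <- reg$cap
    length(reg$basins) <- reg$cap
  }
  p <- profile_raw(k1, n1, K1, reg$alpha, reg$gamma)
  n <- reg$n + 1L
  reg$n <- n
  reg$k[n] <- k1
  reg$nH[n] <- n1
  reg$KD[n] <- K1
  reg$bist[n] <- p$is_bistable
  fp <- p$fixed_points
  reg$basins[[n]] <- list(stable = fp$A[fp$stable], unstable = fp$A[!fp$stable])
  n
}

#' Deterministic CONTROL phenotype with hysteresis
#'
#' In CONTROL simulations the cell life span is long enough for the
#' mean-field dynamics to reach steady state, so the phenotype is the
#' stable fixed point whose basin of attraction contains the inherited
#' protein level. Basins are delimited by the unstable fixed points;
#' a bistable cell therefore stays in the stable state closest to its
#' parental state and never switches spontaneously (hysteresis). An
#' inherited level exactly at an unstable point resolves to the lower
#' stable state.
#'
#' @param g A [genotype()] (or a precomputed [stability_profile()]).
#' @param A_inherited Inherited protein level(s), real `>= 0` (vectorized).
#' @return Steady-state phenotype(s), real.
#' @export
control_phenotype <- function(g, A_inherited) {
  prof <- if (inherits(g, "stability_profile")) g else stability_profile(g)
  fp <- prof$fixed_points
  stable <- fp$A[fp$stable]
  unstable <- fp$A[!fp$stable]
  if (any(A_inherited < 0)) stop("A_inherited must be non-negative")
  if (length(unstable) == 0) return(rep(stable[1], length(A_inherited)))
  idx <- vapply(A_inherited, function(a) sum(unstable < a), integer(1)) + 1L
  stable[idx]
}

# vectorized basin lookup from a registry basin record
basin_phenotype <- function(basin, A_inherited) {
  if (length(basin$unstable) == 0)
    return(rep(basin$stable[1], length(A_inherited)))
  idx <- vapply(A_inherited, function(a) sum(basin$unstable < a), integer(1)) + 1L
  basin$stable[idx]
}

#' Evolutionary run configuration
#'
#' Assembles and validates the full parameter set of an evolutionary
#' simulation. Defaults follow the study conditions of the fluctuating
#' selection experiments: Lorentzian fitness on the end-of-life protein
#' count, tournament selection, spherical multiplicative mutation, life
#' span `tau = 4`, fixed `alpha = 0.25` and `gamma = 1`, and the
#' non-optimal monostable founder `k = 80, n_H = 1, K_D = 10`.
#'
#' @param N Population size (>= 2).
#' @param nu Environmental fluctuation frequency per generation.
#' @param st Tournament size (selection pressure), in `[1, N]`.
#' @param u Mutation probability per cloned cell, in `[0, 1]`.
#' @param M Mutation step-size (maximum fold change, > 1).
#' @param generations Number of generations.
#' @param tau Cell life span (dimensionless time).
#' @param k0,nH0,KD0 Founder genotype.
#' @param alpha,gamma Fixed circuit parameters.
#' @param selection Selection scheme (see [select_next_generation()]).
#' @param mutation_scheme Mutation scheme (see [mutate_genotype()]).
#' @param fitness_shape Fitness shape (see [fitness_score()]).
#' @param phenotype_mode `"final"` (end-of-life count) or `"time_average"`.
#' @param control If `TRUE`, run the deterministic CONTROL model (no
#'   biochemical noise; hysteresis in the bistable region).
#' @param env_mode `"periodic"` or `"stochastic"` fluctuations.
#' @param start_env Starting environment label.
#' @param seed Integer seed for the run (all randomness flows through R's
#'   RNG, so a fixed seed makes the run bit-reproducible).
#' @return Object of class `"evo_config"`.
#' @export
evolution_config <- function(N = 500, nu = 0.1, st = 40, u = 0.03, M = 1.1,
                             generations = 2000, tau = 4,
                             k0 = 80, nH0 = 1, KD0 = 10,
                             alpha = 0.25, gamma = 1,
                             selection = "tournament",
                             mutation_scheme = "spherical",
                             fitness_shape = "lorentzian",
                             phenotype_mode = "final",
                             control = FALSE,
                             env_mode = "periodic",
                             start_env = "LOW",
                             seed = NULL) {
  cfg <- list(N = as.integer(N), nu = nu, st = as.integer(st), u = u, M = M,
              generations = as.integer(generations), tau = tau,
              k0 = k0, nH0 = nH0, KD0 = KD0, alpha = alpha, gamma = gamma,
              selection = selection, mutation_scheme = mutation_scheme,
              fitness_shape = fitness_shape, phenotype_mode = phenotype_mode,
              control = isTRUE(control) || identical(control, "true"),
              env_mode = env_mode, start_env = start_env,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(cfg$N >= 2, "N must be at least 2")
  chk(cfg$st >= 1 && cfg$st <= cfg$N, "st must lie in [1, N]")
  chk(cfg$u >= 0 && cfg$u <= 1, "u must lie in [0, 1]")
  chk(cfg$M > 1, "M must exceed 1")
  chk(cfg$nu > 0 && cfg$nu <= 1, "nu must lie in (0, 1]")
  chk(cfg$generations >= 1, "generations must be positive")
  chk(cfg$tau > 0, "tau must be positive")
  chk(cfg$alpha > 0 && cfg$alpha <= 1, "alpha must be in (0, 1]")
  chk(cfg$gamma > 0, "gamma must be positive")
  chk(cfg$selection %in% c("tournament", "truncation", "proportional"),
      "selection must be one of tournament, truncation, proportional")
  chk(cfg$mutation_scheme %in% c("spherical", "homogeneous_spherical",
                                 "cubic", "1d"),
      "mutation_scheme must be one of spherical, homogeneous_spherical, cubic, 1d")
  chk(cfg$fitness_shape %in% c("lorentzian", "gaussian", "step"),
      "fitness_shape must be one of lorentzian, gaussian, step")
  chk(cfg$phenotype_mode %in% c("final", "time_average"),
      "phenotype_mode must be final or time_average")
  chk(cfg$env_mode %in% c("periodic", "stochastic"),
      "env_mode must be periodic or stochastic")
  chk(cfg$start_env %in% c("LOW", "HIGH"), "start_env must be LOW or HIGH")
  if (cfg$env_mode == "periodic")
    chk(abs(1 / cfg$nu - round(1 / cfg$nu)) < 1e-9,
        "periodic schedule requires an integer epoch length 1/nu")
  b <- genotype_bounds()
  chk(cfg$k0 >= b$k[1] && cfg$k0 <= b$k[2], "k0 outside physiological range")
  chk(cfg$nH0 >= b$n_H[1] && cfg$nH0 <= b$n_H[2], "nH0 outside physiological range")
  chk(cfg$KD0 >= b$K_D[1] && cfg$KD0 <= b$K_D[2], "KD0 outside physiological range")
  structure(cfg, class = "evo_config")
}

#' @export
print.evo_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<evo_config> N = %d, st = %d, u = %g, M = %g, nu = %g, %d generations%s\n",
    "  founder: k = %g, n_H = %g, K_D = %g; tau = %g; %s/%s/%s selection\n"),
    x$N, x$st, x$u, x$M, x$nu, x$generations,
    if (x$control) " [CONTROL]" else "",
    x$k0, x$nH0, x$KD0, x$tau,
    x$selection, x$mutation_scheme, x$fitness_shape))
  invisible(x)
}

#' Run an evolutionary simulation
#'
#' Implements the generational algorithm: starting from an isogenic
#' population at the founder genotype (phenotypes at the deterministic
#' stable state nearest the starting environment's optimum), each
#' generation (1) simulates the gene expression of every cell over its
#' life span from the protein level inherited from its parent (exact SSA,
#' or the deterministic hysteretic steady state in CONTROL mode),
#' (2) scores fitness on the configured phenotype, (3) selects the next
#' generation, (4) mutates each cloned cell with probability `u`, and
#' (5) advances the fluctuating environment at epoch boundaries.
#' Genealogy is recorded throughout and adaptation strategies (ES / BA /
#' GA) are classified at the end of every environmental cycle with at
#' least two completed cycles of history.
#'
#' @param config An [evolution_config()] (or a named list of its fields).
#' @param keep_archive Keep the (pruned) genealogical archive on the
#'   result for inspection (default `FALSE`).
#' @return Object of class `"evo_run"`: list with `generations` (one row
#'   per generation: `g`, `env`, `w`, `f_B`, `mean_k`, `mean_nH`,
#'   `mean_KD`), `cycles` (per complete cycle: `cycle`, `W_cycle`,
#'   `prod_w`, `mean_nH`, `mean_KD`, `mean_fB`), `lineages` (per evaluated
#'   cycle: strategy fractions), `transitions` (strategy transition matrix
#'   averaged over evaluated cycles), and `config`.
#' @export
run_evolution <- function(config, keep_archive = FALSE) {
  cfg <- if (inherits(config, "evo_config")) config else
    do.call(evolution_config, config)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  sched <- env_schedule(cfg$nu, cfg$env_mode, cfg$start_env)
  realized <- schedule_environments(sched, cfg$generations)
  env_seq <- realized$env
  cycle_ends <- realized$cycle_ends
  envs <- list(LOW = env_state("LOW"), HIGH = env_state("HIGH"))

  reg <- new_registry(cfg$alpha, cfg$gamma)
  g0 <- reg_register(reg, cfg$k0, cfg$nH0, cfg$KD0)

  basin0 <- reg$basins[[g0]]
  A_opt0 <- envs[[env_seq[1]]]$A_opt
  founder_A <- basin0$stable[which.min(abs(basin0$stable - A_opt0))]
  if (!cfg$control) founder_A <- round(founder_A)

  N <- cfg$N
  gid <- rep.int(g0, N)
  A_inh <- rep(founder_A, N)

  # archive rows: index g + 1 holds the population of generation g. The
  # founders are the first simulated population (generation 1); generation
  # 0 is the same isogenic population with identity parent links, so
  # lineage windows anchored at "the end of cycle 0" resolve to founders.
  rows <- vector("list", cfg$generations + 1L)
  founder_row <- list(parent = seq_len(N), mutated = rep(FALSE, N), gid = gid)
  rows[[1L]] <- founder_row
  rows[[2L]] <- founder_row

  G <- cfg$generations
  rec_w <- numeric(G); rec_fB <- numeric(G)
  rec_k <- numeric(G); rec_nH <- numeric(G); rec_KD <- numeric(G)
  lineage_rows <- list()
  trans_mats <- list()
  strategies <- c("ES", "BA", "GA", "STATIC")

  for (g in seq_len(G)) {
    env <- envs[[env_seq[g]]]

    # Step 1: gene expression over the life span
    if (cfg$control) {
      pheno <- numeric(N)
      for (grp in split(seq_len(N), gid)) {
        pheno[grp] <- basin_phenotype(reg$basins[[gid[grp[1]]]], A_inh[grp])
      }
      A_final <- pheno
    } else {
      uids <- unique(gid)
      m <- match(gid, uids)
      res <- ssa_population_cpp(reg$k[uids], reg$nH[uids], reg$KD[uids],
                                cfg$alpha, cfg$gamma, m - 1L,
                                as.integer(A_inh), cfg$tau,
                                cfg$phenotype_mode == "time_average")
      A_final <- res$final_A
      pheno <- if (cfg$phenotype_mode == "time_average") res$time_avg_A else
        A_final
    }

    # Step 2: fitness
    fit <- fitness_score(pheno, env, cfg$fitness_shape)
    rec_w[g] <- mean(fit)
    rec_fB[g] <- mean(reg$bist[gid])
    rec_k[g] <- mean(reg$k[gid])
    rec_nH[g] <- mean(reg$nH[gid])
    rec_KD[g] <- mean(reg$KD[gid])

    # lineage classification at cycle ends (needs two prior full cycles)
    ci <- match(g, cycle_ends)
    if (!is.na(ci) && ci >= 2L) {
      ends0 <- c(0L, cycle_ends)  # cycle 0 ends at generation 0
      st <- lineage_stats(rows, reg$bist, e_now = g,
                          e1 = ends0[ci], e2 = ends0[ci - 1L],
                          e3 = if (ci >= 3L) ends0[ci - 2L] else NA_integer_)
      fr <- prop.table(table(factor(st$current, levels = strategies)))
      lineage_rows[[length(lineage_rows) + 1L]] <-
        data.frame(cycle = ci, frac_ES = fr[["ES"]], frac_BA = fr[["BA"]],
                   frac_GA = fr[["GA"]], frac_STATIC = fr[["STATIC"]])
      if (!is.null(st$previous)) {
        tab <- table(factor(st$previous, levels = strategies),
                     factor(st$current, levels = strategies))
        trans_mats[[length(trans_mats) + 1L]] <- unclass(tab)
      }
      # prune archive: rows older than two cycles back are no longer needed
      drop_before <- if (ci >= 3L) ends0[ci - 2L] else 0L
      if (drop_before > 0L)
        for (j in seq_len(drop_before)) rows[j] <- list(NULL)
    }

    if (g == G) break

    # Step 3: selection
    sel <- select_next_generation(fit, cfg$st, cfg$selection)
    gid <- gid[sel]
    A_inh <- A_final[sel]

    # Step 4: mutation of cloned cells
    mut <- stats::runif(N) < cfg$u
    if (any(mut)) {
      nm <- sum(mut)
      e <- mutation_exponents(cfg$mutation_scheme, nm)
      pk <- reg$k[gid[mut]] * cfg$M^e[, "ek"]
      pn <- reg$nH[gid[mut]] * cfg$M^e[, "en"]
      pK <- reg$KD[gid[mut]] * cfg$M^e[, "eK"]
      p <- clamp_params(pk, pn, pK)
      new_ids <- integer(nm)
      for (j in seq_len(nm))
        new_ids[j] <- reg_register(reg, p$k[j], p$n_H[j], p$K_D[j])
      gid[mut] <- new_ids
    }
    rows[[g + 2L]] <- list(parent = sel, mutated = mut, gid = gid)
  }

  generations <- data.frame(g = seq_len(G), env = env_seq, w = rec_w,
                            f_B = rec_fB, mean_k = rec_k, mean_nH = rec_nH,
                            mean_KD = rec_KD)
  cycles <- summarize_cycles(generations, cycle_ends)
  lineages <- if (length(lineage_rows)) do.call(rbind, lineage_rows) else
    data.frame(cycle = integer(), frac_ES = numeric(), frac_BA = numeric(),
               frac_GA = numeric(), frac_STATIC = numeric())
  transitions <- if (length(trans_mats)) {
    total <- Reduce(`+`, trans_mats)
    rs <- rowSums(total)
    sweep(total, 1, ifelse(rs > 0, rs, 1), "/")
  } else NULL

  out <- list(generations = generations, cycles = cycles,
              lineages = lineages, transitions = transitions,
              config = cfg, n_genotypes = reg$n)
  if (keep_archive)
    out$archive <- structure(list(
      rows = rows,
      bistable = reg$bist[seq_len(reg$n)],
      genotypes = data.frame(k = reg$k[seq_len(reg$n)],
                             n_H = reg$nH[seq_len(reg$n)],
                             K_D = reg$KD[seq_len(reg$n)],
                             bistable = reg$bist[seq_len(reg$n)]),
      cycle_ends = cycle_ends),
      class = "lineage_archive")
  class(out) <- "evo_run"
  out
}

#' @export
print.evo_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<evo_run> %d generations, N = %d%s; %d complete cycles, %d genotypes seen\n",
              cfg$generations, cfg$N, if (cfg$control) " [CONTROL]" else "",
              nrow(x$cycles), x$n_genotypes))
  if (nrow(x$cycles)) {
    last <- x$cycles[nrow(x$cycles), ]
    cat(sprintf("  last cycle: W_cycle = %.3f, <n_H> = %.2f, <K_D> = %.1f, <f_B> = %.2f\n",
                last$W_cycle, last$mean_nH, last$mean_KD, last$mean_fB))
  }
  if (nrow(x$lineages)) {
    m <- colMeans(x$lineages[, -1, drop = FALSE])
    cat(sprintf("  strategy fractions (cycle avg): ES %.2f, BA %.2f, GA %.2f, STATIC %.2f\n",
                m[["frac_ES"]], m[["frac_BA"]], m[["frac_GA"]],
                m[["frac_STATIC"]]))
  }
  invisible(x)
}

# per-cycle summaries from the per-generation records
summarize_cycles <- function(generations, cycle_ends) {
  if (length(cycle_ends) == 0)
    return(data.frame(cycle = integer(), W_cycle = numeric(),
                      prod_w = numeric(), mean_nH = numeric(),
                      mean_KD = numeric(), mean_fB = numeric()))
  starts <- c(1L, utils::head(cycle_ends, -1L) + 1L)
  do.call(rbind, lapply(seq_along(cycle_ends), function(ci) {
    idx <- starts[ci]:cycle_ends[ci]
    w <- generations$w[idx]
    data.frame(cycle = ci,
               W_cycle = exp(mean(log(w))),
               prod_w = prod(w),
               mean_nH = mean(generations$mean_nH[idx]),
               mean_KD = mean(generations$mean_KD[idx]),
               mean_fB = mean(generations$f_B[idx]))
  }))
}

#' Geometric-mean fitness summary of one environmental cycle
#'
#' `W_cycle` is the geometric mean of the per-generation population
#' fitness over the cycle, `(prod_g w_g)^(1/L)`; the raw product is also
#' reported.
#'
#' @param w Per-generation population fitness over one complete cycle.
#' @param mean_nH,mean_KD,f_B Optional per-generation means to summarize.
#' @return List with `W_cycle`, `prod_w`, and available means.
#' @examples
#' cycle_summary(c(0.25, 1, 1, 1))$W_cycle  # 0.25^(1/4)
#' @export
cycle_summary <- function(w, mean_nH = NULL, mean_KD = NULL, f_B = NULL) {
  if (any(w < 0 | w > 1)) stop("population fitness must lie in [0, 1]")
  out <- list(W_cycle = exp(mean(log(w))), prod_w = prod(w))
  if (!is.null(mean_nH)) out$mean_nH <- mean(mean_nH)
  if (!is.null(mean_KD)) out$mean_KD <- mean(mean_KD)
  if (!is.null(f_B)) out$mean_fB <- mean(f_B)
  out
}
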