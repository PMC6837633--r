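#' Selective environment
#'
#' The fluctuating selection alternates between two environments: `LOW`
#' selects for an optimal phenotype of 20 proteins and `HIGH` for 80
#' proteins. The Lorentzian fitness width parameter is
#' `eps_sq = 0.2 * A_opt`.
#'
#' @param label `"LOW"` or `"HIGH"`.
#' @param A_opt Optimal phenotype (proteins); defaults 20 / 80 by label.
#' @return Object of class `"env_state"` with `label`, `A_opt`, `eps_sq`.
#' @export
env_state <- function(label = c("LOW", "HIGH"), A_opt = NULL) {
  label <- match.arg(label)
  if (is.null(A_opt)) A_opt <- if (label == "LOW") 20 else 80
  structure(list(label = label, A_opt = A_opt, eps_sq = 0.2 * A_opt),
            class = "env_state")
}

as_env_state <- function(env) {
  if (inherits(env, "env_state")) return(env)
  env_state(env)
}

#' Fitness of a phenotype in an environment
#'
#' The default fitness score is a Lorentzian centred on the environment's
#' optimal phenotype, `omega = eps^2 / (eps^2 + (A - A_opt)^2)` with
#' `eps^2 = 0.2 * A_opt`, so `omega = 1` at the optimum and `omega = 0.5`
#' at a deviation of `eps`. Alternative shapes matched in width: `gaussian`
#' with the same full width at half maximum (`FWHM = 2 * eps`), and `step`
#' equal to 1 on `|A - A_opt| <= 2 * eps` with a small floor (1e-6)
#' elsewhere.
#'
#' @param A Phenotype(s), proteins (vectorized).
#' @param env Environment (label or [env_state()]).
#' @param shape `"lorentzian"` (default), `"gaussian"` or `"step"`.
#' @return Fitness value(s) in `(0, 1]`.
#' @examples
#' fitness_score(84, "HIGH")  # eps^2 = 16, deviation 4 -> 0.5
#' @export
fitness_score <- function(A, env, shape = c("lorentzian", "gaussian", "step")) {
  shape <- match.arg(shape)
  env <- as_env_state(env)
  dev2 <- (A - env$A_opt)^2
  switch(shape,
    lorentzian = env$eps_sq / (env$eps_sq + dev2),
    gaussian = {
      # FWHM = 2*eps  =>  sigma = eps / sqrt(2 log 2)
      sigma2 <- env$eps_sq / (2 * log(2))
      exp(-dev2 / (2 * sigma2))
    },
    step = ifelse(dev2 <= 4 * env$eps_sq, 1, 1e-6)
  )
}

#' Environment fluctuation schedule
#'
#' Periodic mode: the environment switches every `1 / nu` generations
#' (the "epoch"; `1 / nu` must be an integer). Stochastic mode: the
#' environment switches with probability `nu` each generation, so epoch
#' lengths are geometric with mean `1 / nu`. A cycle is one epoch of each
#' environment (starting environment first).
#'
#' @param nu Fluctuation frequency per generation (0 < nu <= 1).
#' @param mode `"periodic"` or `"stochastic"`.
#' @param start_env Starting environment label (default `"LOW"`).
#' @return Object of class `"env_schedule"`.
#' @export
env_schedule <- function(nu, mode = c("periodic", "stochastic"),
                         start_env = c("LOW", "HIGH")) {
  mode <- match.arg(mode)
  start_env <- match.arg(start_env)
  if (nu <= 0 || nu > 1) stop("nu must be in (0, 1]")
  if (mode == "periodic" && abs(1 / nu - round(1 / nu)) > 1e-9)
    stop("periodic schedule requires an integer epoch length 1/nu")
  structure(list(nu = nu, mode = mode, start_env = start_env),
            class = "env_schedule")
}

#' Realize an environment schedule over a run
#'
#' Draws (stochastic mode) or lays out (periodic mode) the environment
#' label of every generation, together with epoch boundaries and the
#' generations at which complete cycles (one epoch of each environment)
#' end.
#'
#' @param schedule An [env_schedule()].
#' @param generations Number of generations.
#' @return List with `env` (character vector per generation), `cycle_ends`
#'   (generation indices closing each complete cycle), and `n_cycles`.
#' @examples
#' s <- env_schedule(nu = 0.1)
#' schedule_environments(s, 10000)$n_cycles  # 500
#' @export
schedule_environments <- function(schedule, generations) {
  stopifnot(inherits(schedule, "env_schedule"))
  labs <- c("LOW", "HIGH")
  start <- match(schedule$start_env, labs)
  if (schedule$mode == "periodic") {
    L <- round(1 / schedule$nu)
    epoch_idx <- ((seq_len(generations) - 1L) %/% L)
    env <- labs[((start - 1L + epoch_idx) %% 2L) + 1L]
    switches <- which(diff(epoch_idx) == 1L)  # generation before each switch
    epoch_ends <- seq(L, generations, by = L)
  } else {
    flips <- stats::runif(generations) < schedule$nu
    # flip decided at the end of each generation
    state <- (start - 1L + cumsum(c(0L, flips[-generations]))) %% 2L
    env <- labs[state + 1L]
    epoch_ends <- which(flips)
  }
  cycle_ends <- epoch_ends[seq_along(epoch_ends) %% 2L == 0L]
  cycle_ends <- cycle_ends[cycle_ends <= generations]
  list(env = env, cycle_ends = cycle_ends, n_cycles = length(cycle_ends))
}

#' Environment of a given generation under a periodic schedule
#'
#' Convenience accessor equivalent to indexing
#' [schedule_environments()]`$env`.
#'
#' @param schedule An [env_schedule()] (periodic mode).
#' @param g Generation index (1-based).
#' @return `"LOW"` or `"HIGH"`.
#' @export
environment_at <- function(schedule, g) {
  stopifnot(inherits(schedule, "env_schedule"))
  if (schedule$mode != "periodic")
    stop("environment_at() is defined for periodic schedules; realize a stochastic schedule with schedule_environments()")
  labs <- c("LOW", "HIGH")
  start <- match(schedule$start_env, labs)
  L <- round(1 / schedule$nu)
  epoch_idx <- (g - 1L) %/% L
  labs[((start - 1L + epoch_idx) %% 2L) + 1L]
}
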