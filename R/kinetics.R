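#' Exact stochastic simulation of one cell life span
#'
#' Gillespie direct-method simulation of the one-species birth-death
#' process: protein synthesis `A -> A + 1` with propensity `f(A)` (see
#' [synthesis_rate()]) and degradation `A -> A - 1` with propensity
#' `gamma * A`. Waiting times are exponential with rate `f(A) + gamma * A`
#' and the next event is synthesis with probability `f(A) / (f(A) + gamma*A)`.
#' At `A = 0` only synthesis can fire (its propensity `k * alpha` is
#' positive). Randomness is drawn from R's RNG, so runs are reproducible
#' under `set.seed()`.
#'
#' @param g A [genotype()].
#' @param A0 Initial protein count (integer >= 0).
#' @param tau_end Life span in dimensionless time (default 4, the value
#'   used throughout the stochastic simulations).
#' @param record If `TRUE`, return the full event record.
#' @return Object of class `"trajectory"`: list with `final_A`,
#'   `time_avg_A`, and, when `record = TRUE`, `times` and `states`.
#' @examples
#' set.seed(1)
#' simulate_cell(genotype(80, 1, 10), A0 = 20, tau_end = 4)$final_A
#' @export
simulate_cell <- function(g, A0, tau_end = 4, record = FALSE) {
  stopifnot(inherits(g, "genotype"))
  if (A0 < 0) stop("A0 must be non-negative")
  if (tau_end <= 0) stop("tau_end must be positive")
  if (record) {
    tr <- ssa_trajectory_cpp(g$k, g$n_H, g$K_D, g$alpha, g$gamma,
                             as.integer(A0), tau_end)
  } else {
    res <- ssa_population_cpp(g$k, g$n_H, g$K_D, g$alpha, g$gamma,
                              0L, as.integer(A0), tau_end, TRUE)
    tr <- list(times = NULL, states = NULL,
               final_A = res$final_A[1], time_avg_A = res$time_avg_A[1])
  }
  tr$tau_end <- tau_end
  class(tr) <- "trajectory"
  tr
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> tau_end = %g, final_A = %d, time_avg_A = %.3f%s\n",
              x$tau_end, x$final_A, x$time_avg_A,
              if (is.null(x$times)) "" else
                sprintf(", %d events recorded", length(x$times) - 1L)))
  invisible(x)
}

#' Write a recorded trajectory as two-column delimited text
#'
#' @param x A `"trajectory"` with a recorded event list.
#' @param path Output file; columns `tau` and `A`, tab-separated.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "trajectory"))
  if (is.null(x$times)) stop("trajectory was simulated without record = TRUE")
  utils::write.table(data.frame(tau = x$times, A = x$states), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monte-Carlo distribution of the end-of-life protein count
#'
#' Runs `n_reps` independent cell life spans from the same initial count
#' and returns the normalized histogram of final counts as a
#' [distribution_vector()].
#'
#' @inheritParams simulate_cell
#' @param n_reps Number of replicate cells (>= 1).
#' @param A_max State-space bound of the returned histogram; defaults to a
#'   comfortable margin above the largest observed count.
#' @return A `"distribution_vector"` over `0..A_max` summing to 1.
#' @export
empirical_distribution <- function(g, A0, tau_end = 4, n_reps, A_max = NULL) {
  stopifnot(inherits(g, "genotype"), n_reps >= 1)
  res <- ssa_population_cpp(g$k, g$n_H, g$K_D, g$alpha, g$gamma,
                            rep(0L, n_reps), rep(as.integer(A0), n_reps),
                            tau_end, FALSE)
  finals <- res$final_A
  if (is.null(A_max)) A_max <- max(finals) + 10L
  probs <- tabulate(pmin(finals, A_max) + 1L, nbins = A_max + 1L) / n_reps
  distribution_vector(probs, A_max)
}
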