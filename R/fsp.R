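#' Probability mass over protein counts
#'
#' Container for a (possibly sub-normalized) distribution over the
#' truncated state space `A = 0..A_max`. Finite state projection may leak
#' probability past the truncation boundary; the leaked mass `1 - sum(probs)`
#' is tracked.
#'
#' @param probs Non-negative masses for states `0..A_max`.
#' @param A_max Truncation bound (integer, `length(probs) == A_max + 1`).
#' @return Object of class `"distribution_vector"`.
#' @export
distribution_vector <- function(probs, A_max = length(probs) - 1L) {
  stopifnot(length(probs) == A_max + 1L)
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (sum(probs) > 1 + 1e-9) stop("total mass exceeds 1")
  structure(list(probs = as.numeric(probs), A_max = as.integer(A_max),
                 leak = max(0, 1 - sum(probs))),
            class = "distribution_vector")
}

#' @export
print.distribution_vector <- function(x, ...) {
  m <- sum((0:x$A_max) * x$probs) / max(sum(x$probs), .Machine$double.eps)
  cat(sprintf("<distribution_vector> states 0..%d, mass %.6f (leak %.2e), mean %.2f\n",
              x$A_max, sum(x$probs), x$leak, m))
  invisible(x)
}

# point mass at integer state a on 0..A_max
point_mass <- function(a, A_max) {
  probs <- numeric(A_max + 1L)
  probs[a + 1L] <- 1
  distribution_vector(probs, A_max)
}

#' Truncated CME generator of the birth-death process
#'
#' Builds the tridiagonal rate operator of the chemical master equation on
#' states `0..A_max`: off-diagonals hold the birth rates `f(a)` (a -> a+1)
#' and death rates `gamma * a` (a -> a-1); the diagonal holds
#' `-(f(a) + gamma * a)` everywhere, but the birth transition out of the
#' truncation boundary `A_max` is dropped (absorbing truncation), so
#' interior column sums are 0 and the boundary column sum is
#' `-f(A_max)` -- probability crossing the boundary is lost and tracked as
#' leak.
#'
#' @param g A [genotype()].
#' @param A_max Truncation bound (>= 1).
#' @return Object of class `"fsp_generator"` with elements `birth`, `death`
#'   (rate vectors over `0..A_max`), `A_max`, and the genotype. Use
#'   `as.matrix()` for the dense operator.
#' @export
build_generator <- function(g, A_max) {
  stopifnot(inherits(g, "genotype"), A_max >= 1)
  a <- 0:A_max
  birth <- hill_f(a, g$k, g$n_H, g$K_D, g$alpha)
  death <- g$gamma * a
  structure(list(birth = birth, death = death, A_max = as.integer(A_max),
                 genotype = g),
            class = "fsp_generator")
}

#' @export
as.matrix.fsp_generator <- function(x, ...) {
  n <- x$A_max + 1L
  B <- matrix(0, n, n)
  diag(B) <- -(x$birth + x$death)
  B[cbind(2:n, 1:(n - 1))] <- x$birth[1:(n - 1)]   # a -> a+1
  B[cbind(1:(n - 1), 2:n)] <- x$death[2:n]          # a -> a-1
  B
}

#' @export
print.fsp_generator <- function(x, ...) {
  cat(sprintf("<fsp_generator> tridiagonal CME operator on states 0..%d\n",
              x$A_max))
  invisible(x)
}

#' Propagate a distribution through the matrix exponential of the generator
#'
#' Computes `exp(B * tau) %*% rho0` by uniformization with a series
#' truncation error below `tol` in the 1-norm (segmented so Poisson weights
#' stay in floating-point range). Probability that crosses the truncation
#' boundary is absorbed and reported as `leak` on the result.
#'
#' @param gen An [build_generator()] operator.
#' @param rho0 A [distribution_vector()] on the same state space.
#' @param tau Propagation time (>= 0).
#' @param tol Series truncation tolerance (default 1e-12).
#' @param max_leak If the truncation leak exceeds this bound, signal a
#'   condition of class `"fsp_truncation_error"` so callers can enlarge
#'   `A_max`. Default `Inf` (no check).
#' @return A `"distribution_vector"`.
#' @export
propagate_fsp <- function(gen, rho0, tau, tol = 1e-12, max_leak = Inf) {
  stopifnot(inherits(gen, "fsp_generator"), inherits(rho0, "distribution_vector"))
  if (rho0$A_max != gen$A_max) stop("state spaces differ")
  out <- fsp_propagate_cpp(gen$birth, gen$death, rho0$probs, tau, tol)
  out[out < 1e-12] <- pmax(out[out < 1e-12], 0)
  d <- distribution_vector(out, gen$A_max)
  if (d$leak > max_leak) {
    stop(structure(class = c("fsp_truncation_error", "error", "condition"),
                   list(message = sprintf(
                     "FSP truncation insufficient: leak %.3e exceeds %.3e at A_max = %d",
                     d$leak, max_leak, gen$A_max), call = NULL)))
  }
  d
}

#' Stationary distribution of the birth-death process
#'
#' The one-dimensional birth-death chain satisfies detailed balance, so its
#' stationary law has the product form
#' `pi(a) proportional to prod_{j=1..a} f(j-1) / (gamma * j)`,
#' computed here in log space and normalized. With a constant birth rate
#' (`alpha = 1`) this is Poisson with mean `k / gamma`.
#'
#' @param g A [genotype()].
#' @param A_max Truncation bound; if `NULL`, chosen so the omitted tail is
#'   below 1e-14 relative to the mode.
#' @return A `"distribution_vector"` summing to 1.
#' @export
stationary_distribution <- function(g, A_max = NULL) {
  stopifnot(inherits(g, "genotype"))
  auto <- is.null(A_max)
  if (auto) A_max <- max(150L, ceiling(2 * g$k / g$gamma))
  repeat {
    a <- 1:A_max
    logpi <- c(0, cumsum(log(hill_f(a - 1, g$k, g$n_H, g$K_D, g$alpha)) -
                           log(g$gamma * a)))
    logpi <- logpi - max(logpi)
    if (!auto || logpi[A_max + 1L] < log(1e-14)) break
    A_max <- 2L * A_max
  }
  probs <- exp(logpi)
  distribution_vector(probs / sum(probs), A_max)
}

# propagate a point mass under genotype g, doubling A_max until the leak
# is below leak_tol; returns the distribution
propagate_point <- function(g, A0, tau, leak_tol = 1e-8) {
  A_max <- max(150L, ceiling(2 * g$k / g$gamma), A0 + 10L)
  repeat {
    gen <- build_generator(g, A_max)
    d <- propagate_fsp(gen, point_mass(A0, A_max), tau)
    if (d$leak <= leak_tol) return(d)
    if (A_max > 5e4) stop("FSP truncation bound grew unreasonably large")
    A_max <- 2L * A_max
  }
}

#' Noise load of a genotype in an environment
#'
#' The noise load is the expected decline in fitness over one cell life
#' span caused purely by stochastic gene expression: starting from the
#' optimal phenotype (`rho0` a point mass at the environment's optimum
#' `A^(E)`), the distribution is propagated for `tau` and the expected
#' fitness `E[omega] = sum_a omega(a) * rho(a, tau)` is evaluated;
#' `noise_load = 1 - E[omega]`. This expected fitness is also the fitness
#' of an infinite isogenic population after one generation under perfect
#' selection and no mutation.
#'
#' @param g A [genotype()].
#' @param env An [env_state()] (or label `"LOW"` / `"HIGH"`).
#' @param tau Life span (default 4).
#' @param fitness Fitness function of the protein count; defaults to the
#'   Lorentzian [fitness_score()] for `env`.
#' @return List with `noise_load`, `expected_fitness`
#'   (`noise_load = 1 - expected_fitness` identically), and `leak`.
#' @export
noise_load <- function(g, env, tau = 4, fitness = NULL) {
  env <- as_env_state(env)
  d <- propagate_point(g, env$A_opt, tau)
  omega <- if (is.null(fitness)) fitness_score(0:d$A_max, env) else
    fitness(0:d$A_max)
  ef <- sum(omega * d$probs)
  list(noise_load = 1 - ef, expected_fitness = ef, leak = d$leak)
}

#' Epimutation probability between environments
#'
#' Probability that a cell carrying genotype `g`, selected at the optimal
#' phenotype of `env_from`, displays a good fitness score in the alternative
#' environment at the end of its life span:
#' `P[omega^(env_to)(A_tau) >= 0.5 | A_0 = A^(env_from)]`,
#' computed from the FSP distribution by summing mass over the integer
#' states where the (exact, uninterpolated) Lorentzian fitness of `env_to`
#' is at least 0.5. For a bistable genotype this approximates the
#' probability of a noise-induced switch between expression states.
#'
#' @param g A [genotype()].
#' @param env_from,env_to Distinct environments (labels or [env_state()]).
#' @param tau Life span (default 4).
#' @return Probability in `[0, 1]`.
#' @export
epimutation_probability <- function(g, env_from, env_to, tau = 4) {
  env_from <- as_env_state(env_from)
  env_to <- as_env_state(env_to)
  if (env_from$label == env_to$label)
    stop("env_from and env_to must differ")
  d <- propagate_point(g, env_from$A_opt, tau)
  omega_to <- fitness_score(0:d$A_max, env_to)
  sum(d$probs[omega_to >= 0.5])
}

#' Noise-load and epimutation maps over the solution-genotype grid
#'
#' For every `(n_H, K_D)` on a grid, computes the solution genotype of each
#' environment (synthesis rate from [solution_k()] placing the environment's
#' optimum at a fixed point), then, where valid, the FSP noise load at
#' `tau` and the epimutation probability toward the alternative environment.
#'
#' @param n_H,K_D Grid coordinate vectors (defaults: log-spaced, 40 points
#'   in `[1, 16]` and 48 points in `[1, 120]`).
#' @param envs Environments to map (default both).
#' @param tau Life span (default 4).
#' @param alpha,gamma Fixed circuit parameters.
#' @return data.frame with columns `n_H`, `K_D`, `env`, `k_star`, `valid`,
#'   `noise_load`, `epimutation_prob` (`NA` where the solution genotype is
#'   invalid).
#' @export
noise_load_map <- function(n_H = map_grid()$n_H, K_D = map_grid()$K_D,
                           envs = c("LOW", "HIGH"), tau = 4,
                           alpha = 0.25, gamma = 1) {
  cells <- expand.grid(n_H = n_H, K_D = K_D, env = envs,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  other <- c(LOW = "HIGH", HIGH = "LOW")
  res <- lapply(seq_len(nrow(cells)), function(i) {
    env <- as_env_state(cells$env[i])
    sk <- solution_k(env$A_opt, cells$n_H[i], cells$K_D[i], alpha, gamma)
    if (!sk$valid)
      return(data.frame(k_star = sk$k_star, valid = FALSE,
                        noise_load = NA_real_, epimutation_prob = NA_real_))
    g <- genotype(sk$k_star, cells$n_H[i], cells$K_D[i], alpha, gamma)
    d <- propagate_point(g, env$A_opt, tau)
    omega <- fitness_score(0:d$A_max, env)
    omega_alt <- fitness_score(0:d$A_max, as_env_state(other[[env$label]]))
    data.frame(k_star = sk$k_star, valid = TRUE,
               noise_load = 1 - sum(omega * d$probs),
               epimutation_prob = sum(d$probs[omega_alt >= 0.5]))
  })
  cbind(cells[, c("n_H", "K_D", "env")], do.call(rbind, res))
}

#' Default analysis grid over the nonlinearity / dissociation plane
#'
#' Log-spaced grid covering `n_H` in `[1, 16]` (40 points) and `K_D` in
#' `[1, 120]` (48 points), the axes ranges of the genetic-potential and
#' noise-load maps.
#'
#' @param n_nH,n_KD Number of grid points per axis.
#' @return List with vectors `n_H` and `K_D`.
#' @export
map_grid <- function(n_nH = 40, n_KD = 48) {
  list(n_H = exp(seq(log(1), log(16), length.out = n_nH)),
       K_D = exp(seq(log(1), log(120), length.out = n_KD)))
}
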