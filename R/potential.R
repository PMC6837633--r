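#' Mutational distance between two genotypes
#'
#' The distance, in units of one maximal mutation step, between two
#' genotypes: the Euclidean norm of the componentwise difference of
#' `(log k, log n_H, log K_D)` divided by `log M` (i.e. the Euclidean
#' distance in log-base-M coordinates). A single spherical mutation moves
#' a genotype a distance of at most 1.
#'
#' @param a,b [genotype()]s (strictly positive parameters).
#' @param M Mutation step-size (> 1).
#' @return Non-negative distance.
#' @export
mutational_distance <- function(a, b, M) {
  stopifnot(inherits(a, "genotype"), inherits(b, "genotype"))
  if (M <= 1) stop("M must exceed 1")
  sqrt((log(a$k) - log(b$k))^2 +
         (log(a$n_H) - log(b$n_H))^2 +
         (log(a$K_D) - log(b$K_D))^2) / log(M)
}

#' Solution-genotype manifold of one environment
#'
#' For every `(n_H, K_D)` on the grid, the synthesis rate `k*` that places
#' the environment's optimal phenotype at a fixed point ([solution_k()]),
#' with `valid` marking cells where that fixed point is stable and `k*`
#' lies within the physiological bounds.
#'
#' @param env Environment (label or [env_state()]).
#' @param n_H,K_D Grid coordinate vectors (defaults [map_grid()]).
#' @param alpha,gamma Fixed circuit parameters.
#' @return data.frame with columns `n_H`, `K_D`, `env`, `k_star`,
#'   `valid`, `bistable`.
#' @export
solution_manifold <- function(env, n_H = map_grid()$n_H, K_D = map_grid()$K_D,
                              alpha = 0.25, gamma = 1) {
  env <- as_env_state(env)
  cells <- expand.grid(n_H = n_H, K_D = K_D, KEEP.OUT.ATTRS = FALSE)
  k_star <- numeric(nrow(cells))
  valid <- logical(nrow(cells))
  bist <- logical(nrow(cells))
  b <- genotype_bounds()
  for (i in seq_len(nrow(cells))) {
    An <- env$A_opt^cells$n_H[i]
    Kn <- cells$K_D[i]^cells$n_H[i]
    ks <- gamma * env$A_opt * (An + Kn) / (An + alpha * Kn)
    k_star[i] <- ks
    if (ks >= b$k[1] && ks <= b$k[2]) {
      prof <- profile_raw(ks, cells$n_H[i], cells$K_D[i], alpha, gamma)
      fp <- prof$fixed_points
      j <- which.min(abs(fp$A - env$A_opt))
      valid[i] <- abs(fp$A[j] - env$A_opt) <= 1e-3 * max(1, env$A_opt) &&
        fp$stable[j]
      bist[i] <- prof$is_bistable
    }
  }
  data.frame(n_H = cells$n_H, K_D = cells$K_D, env = env$label,
             k_star = k_star, valid = valid, bistable = bist)
}

#' Genetic-potential map over the nonlinearity / dissociation plane
#'
#' For every `(n_H, K_D)` grid cell, the genetic potential of each
#' environment's solution genotype is the minimum mutational distance
#' ([mutational_distance()]) from it to *any valid* solution genotype of
#' the alternative environment (minimized over the discretized manifold).
#' `combined = min(d_L, d_H)` is smallest around the bistable region,
#' where a single genotype solves both environments; cells with
#' `combined <= 1` are adaptable in a single mutation of step-size `M`.
#'
#' @param n_H,K_D Grid coordinate vectors (defaults [map_grid()]).
#' @param M Mutation step-size (> 1).
#' @param alpha,gamma Fixed circuit parameters.
#' @return data.frame with columns `n_H`, `K_D`, `k_L`, `k_H`, `valid_L`,
#'   `valid_H`, `bistable_L`, `bistable_H`, `d_L`, `d_H`, `combined`
#'   (distances `NA` where the cell's own solution genotype is invalid).
#' @export
potential_map <- function(n_H = map_grid()$n_H, K_D = map_grid()$K_D,
                          M = 1.1, alpha = 0.25, gamma = 1) {
  if (M <= 1) stop("M must exceed 1")
  mL <- solution_manifold("LOW", n_H, K_D, alpha, gamma)
  mH <- solution_manifold("HIGH", n_H, K_D, alpha, gamma)
  if (!any(mL$valid) || !any(mH$valid))
    stop("a solution manifold is empty on this grid")
  d_L <- min_cross_distance(mL, mH, M)
  d_H <- min_cross_distance(mH, mL, M)
  combined <- pmin(d_L, d_H, na.rm = TRUE)  # NA only where both are invalid
  data.frame(n_H = mL$n_H, K_D = mL$K_D,
             k_L = mL$k_star, k_H = mH$k_star,
             valid_L = mL$valid, valid_H = mH$valid,
             bistable_L = mL$bistable, bistable_H = mH$bistable,
             d_L = d_L, d_H = d_H, combined = combined)
}

# per cell of manifold `from`, minimum log-M distance to any valid cell of
# manifold `to`; NA where the `from` cell is itself invalid
min_cross_distance <- function(from, to, M) {
  ok <- to$valid
  lk_t <- log(to$k_star[ok]); ln_t <- log(to$n_H[ok]); lK_t <- log(to$K_D[ok])
  out <- rep(NA_real_, nrow(from))
  src <- which(from$valid)
  if (length(src) == 0 || length(lk_t) == 0) return(out)
  lk <- log(from$k_star[src]); ln <- log(from$n_H[src]); lK <- log(from$K_D[src])
  # chunk the cross-distance matrix so large grids stay within memory
  res <- numeric(length(src))
  for (b in split(seq_along(src), ceiling(seq_along(src) / 512))) {
    d2 <- outer(lk[b], lk_t, `-`)^2 + outer(ln[b], ln_t, `-`)^2 +
      outer(lK[b], lK_t, `-`)^2
    res[b] <- sqrt(do.call(pmin, as.data.frame(d2)))
  }
  out[src] <- res / log(M)
  out
}

#' Genetic-potential map for the toggle-switch circuit
#'
#' The analogue of [potential_map()] for the mutual-repression circuit:
#' the grid runs over `(n_A, K_A)` of the selected gene, the solution
#' synthesis rate comes from [toggle_solution_kA()], and distances are
#' Euclidean in `(log k_A, log n_A, log K_A)` scaled by `log M`.
#'
#' @param n_A,K_A Grid coordinate vectors.
#' @param M Mutation step-size (> 1).
#' @param ... Passed to [toggle_genotype()] (repressor parameters).
#' @return data.frame in the same layout as [potential_map()].
#' @export
toggle_potential_map <- function(n_A = map_grid()$n_H, K_A = map_grid()$K_D,
                                 M = 1.1, ...) {
  if (M <= 1) stop("M must exceed 1")
  manifold <- function(env) {
    env <- as_env_state(env)
    cells <- expand.grid(n_H = n_A, K_D = K_A, KEEP.OUT.ATTRS = FALSE)
    k_star <- numeric(nrow(cells)); valid <- logical(nrow(cells))
    bist <- logical(nrow(cells))
    for (i in seq_len(nrow(cells))) {
      tg <- toggle_genotype(k_A = 1, n_A = cells$n_H[i], K_A = cells$K_D[i], ...)
      sol <- toggle_solution_kA(env$A_opt, tg)
      k_star[i] <- sol$k_star
      valid[i] <- sol$valid
      if (sol$valid) {
        tg$k_A <- sol$k_star
        bist[i] <- toggle_stability_profile(tg)$is_bistable
      }
    }
    data.frame(n_H = cells$n_H, K_D = cells$K_D, env = env$label,
               k_star = k_star, valid = valid, bistable = bist)
  }
  mL <- manifold("LOW")
  mH <- manifold("HIGH")
  if (!any(mL$valid) || !any(mH$valid))
    stop("a toggle solution manifold is empty on this grid")
  d_L <- min_cross_distance(mL, mH, M)
  d_H <- min_cross_distance(mH, mL, M)
  combined <- pmin(d_L, d_H, na.rm = TRUE)  # NA only where both are invalid
  data.frame(n_A = mL$n_H, K_A = mL$K_D,
             k_L = mL$k_star, k_H = mH$k_star,
             valid_L = mL$valid, valid_H = mH$valid,
             bistable_L = mL$bistable, bistable_H = mH$bistable,
             d_L = d_L, d_H = d_H, combined = combined)
}
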