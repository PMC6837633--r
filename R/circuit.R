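#' Hill-type synthesis rate of the self-activating gene
#'
#' The protein synthesis propensity
#' `f(A) = k * (alpha + (1 - alpha) * A^n_H / (A^n_H + K_D^n_H))`,
#' a monotone non-decreasing function of the activator copy number bounded
#' in `[k * alpha, k]`.
#'
#' @param g A [genotype()].
#' @param A Protein copy number(s), real, `>= 0` (vectorized).
#' @return Synthesis rate(s), same length as `A`.
#' @export
synthesis_rate <- function(g, A) {
  stopifnot(inherits(g, "genotype"))
  if (any(A < 0)) stop("A must be non-negative")
  hill_f(A, g$k, g$n_H, g$K_D, g$alpha)
}

# vectorized over A; raw parameters (internal hot path)
hill_f <- function(A, k, n_H, K_D, alpha) {
  An <- A^n_H
  k * (alpha + (1 - alpha) * An / (An + K_D^n_H))
}

#' Fixed points and stability of the deterministic circuit
#'
#' Finds all roots of `f(A) - gamma * A = 0` on `[0, 1.05 * k / gamma]` for
#' the mean-field dynamics `dA/dt = f(A) - gamma * A`. Roots are bracketed
#' on a combined linear + log-spaced grid (>= 2000 points, robust for
#' near-tangent bifurcation cases) and refined by bisection to an absolute
#' tolerance of 1e-6 proteins. A root is stable iff the flow changes sign
#' from positive to negative across it. Because `f(0) = k * alpha > 0` and
#' `f` is bounded by `k`, at least one fixed point always exists, the number
#' of sign-change roots is odd, and the first and last are stable.
#'
#' @param g A [genotype()].
#' @return Object of class `"stability_profile"`: list with `fixed_points`
#'   (data.frame with columns `A` and `stable`, sorted ascending),
#'   `n_stable`, and `is_bistable` (`n_stable >= 2`).
#' @examples
#' stability_profile(genotype(80, 1, 10))   # one stable point near 72.75
#' @export
stability_profile <- function(g) {
  stopifnot(inherits(g, "genotype"))
  profile_raw(g$k, g$n_H, g$K_D, g$alpha, g$gamma)
}

# internal: stability profile from raw parameters (cached by the engine)
profile_raw <- function(k, n_H, K_D, alpha, gamma, tol = 1e-6) {
  upper <- 1.05 * k / gamma
  # linear grid resolves high-copy roots; log grid resolves roots near zero
  grid <- unique(sort(c(
    seq(0, upper, length.out = 1600),
    exp(seq(log(max(upper * 1e-6, 1e-8)), log(upper), length.out = 600))
  )))
  gval <- hill_f(grid, k, n_H, K_D, alpha) - gamma * grid
  sg <- sign(gval)
  # treat exact zeros on the grid as members of the following interval
  sg[sg == 0] <- 1
  idx <- which(sg[-1] != sg[-length(sg)])
  if (length(idx) == 0) {
    # flow positive at 0 and negative at the upper bound: cannot happen,
    # but guard against degenerate numerics
    stop("no sign change found in the flow; degenerate genotype")
  }
  lo <- grid[idx]
  hi <- grid[idx + 1]
  # vectorized bisection over all brackets
  n_iter <- ceiling(log2(max((hi - lo) / tol, 1))) + 2
  flo <- gval[idx]
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    fmid <- hill_f(mid, k, n_H, K_D, alpha) - gamma * mid
    take_left <- (sign(fmid) == sign(flo)) & (fmid != 0)
    lo <- ifelse(take_left, mid, lo)
    flo <- ifelse(take_left, fmid, flo)
    hi <- ifelse(take_left, hi, mid)
  }
  roots <- (lo + hi) / 2
  # stable iff flow goes + -> - across the root; flow at 0 is positive so
  # roots alternate stable/unstable starting stable
  stable <- sg[idx] > 0
  structure(list(
    fixed_points = data.frame(A = roots, stable = stable),
    n_stable = sum(stable),
    is_bistable = sum(stable) >= 2
  ), class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat(sprintf("<stability_profile> %d fixed point(s), %d stable; %s\n",
              nrow(x$fixed_points), x$n_stable,
              if (x$is_bistable) "bistable" else "monostable"))
  fp <- x$fixed_points
  for (i in seq_len(nrow(fp)))
    cat(sprintf("  A* = %10.4f  (%s)\n", fp$A[i],
                if (fp$stable[i]) "stable" else "unstable"))
  invisible(x)
}

#' Synthesis rate that places a fixed point at a target expression level
#'
#' For a target steady state `A_star` and given `n_H`, `K_D`, the synthesis
#' rate making `A_star` a fixed point of the deterministic dynamics is
#' uniquely
#' `k_star = gamma * A_star * (A_star^n_H + K_D^n_H) / (A_star^n_H + alpha * K_D^n_H)`.
#' The resulting genotype is a *solution genotype* for an environment whose
#' optimal phenotype is `A_star` only if that fixed point is stable and
#' `k_star` lies within the physiological bounds; `valid` reports both
#' checks.
#'
#' @param A_star Target steady state (proteins, > 0).
#' @param n_H,K_D,alpha,gamma Circuit parameters.
#' @return List with `k_star` and `valid`.
#' @examples
#' solution_k(80, n_H = 1, K_D = 10)$k_star  # 80 * 90 / 82.5 = 87.2727...
#' @export
solution_k <- function(A_star, n_H, K_D, alpha = 0.25, gamma = 1) {
  if (A_star <= 0) stop("A_star must be positive")
  An <- A_star^n_H
  Kn <- K_D^n_H
  k_star <- gamma * A_star * (An + Kn) / (An + alpha * Kn)
  b <- genotype_bounds()
  valid <- k_star >= b$k[1] && k_star <= b$k[2]
  if (valid) {
    prof <- profile_raw(k_star, n_H, K_D, alpha, gamma)
    fp <- prof$fixed_points
    j <- which.min(abs(fp$A - A_star))
    valid <- abs(fp$A[j] - A_star) <= 1e-3 * max(1, A_star) && fp$stable[j]
  }
  list(k_star = k_star, valid = valid)
}
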