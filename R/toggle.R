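#' Construct a toggle-switch genotype
#'
#' A two-gene mutual-repression circuit ("toggle switch"): the selected gene
#' A is repressed by B, and B is repressed by A. With the repressor at quasi
#' steady state, `B*(A) = (k_B / gamma) * (alpha_B + (1 - alpha_B) *
#' K_B^n_B / (K_B^n_B + A^n_B))`, the effective synthesis rate of A is
#' `f(A) = k_A * (alpha_A + (1 - alpha_A) * K_A^n_A / (K_A^n_A + B*(A)^n_A))`,
#' a one-variable reduction whose fixed points and stability are analysed
#' exactly as for the self-activator.
#'
#' @param k_A,alpha_A,K_A,n_A Parameters of the selected gene A.
#' @param k_B,alpha_B,K_B,n_B Parameters of the repressor B.
#' @param gamma Shared degradation rate constant.
#' @return Object of class `"toggle_genotype"`.
#' @export
toggle_genotype <- function(k_A, n_A, K_A, alpha_A = 0.25,
                            k_B = 50, alpha_B = 0.2, K_B = 20, n_B = 5,
                            gamma = 1) {
  vals <- c(k_A = k_A, n_A = n_A, K_A = K_A, alpha_A = alpha_A,
            k_B = k_B, alpha_B = alpha_B, K_B = K_B, n_B = n_B,
            gamma = gamma)
  if (any(vals <= 0)) stop("all toggle parameters must be positive")
  if (alpha_A > 1 || alpha_B > 1) stop("basal fractions must be <= 1")
  structure(as.list(vals), class = "toggle_genotype")
}

# quasi-steady repressor level B*(A), vectorized over A
toggle_repressor <- function(tg, A) {
  Kn <- tg$K_B^tg$n_B
  (tg$k_B / tg$gamma) * (tg$alpha_B + (1 - tg$alpha_B) * Kn / (Kn + A^tg$n_B))
}

# effective synthesis rate of gene A after the quasi-steady-state reduction
toggle_f <- function(tg, A) {
  B <- toggle_repressor(tg, A)
  Kn <- tg$K_A^tg$n_A
  tg$k_A * (tg$alpha_A + (1 - tg$alpha_A) * Kn / (Kn + B^tg$n_A))
}

#' Fixed points and stability of the reduced toggle switch
#'
#' Applies the same bracketing + bisection scheme as [stability_profile()]
#' to the reduced flow `f(A) - gamma * A`, with `f` the effective synthesis
#' rate of the selected gene under quasi-steady repression (see
#' [toggle_genotype()]).
#'
#' @param tg A [toggle_genotype()].
#' @return A `"stability_profile"` object.
#' @export
toggle_stability_profile <- function(tg) {
  stopifnot(inherits(tg, "toggle_genotype"))
  tol <- 1e-6
  upper <- 1.05 * tg$k_A / tg$gamma
  grid <- unique(sort(c(
    seq(0, upper, length.out = 1600),
    exp(seq(log(max(upper * 1e-6, 1e-8)), log(upper), length.out = 600))
  )))
  gval <- toggle_f(tg, grid) - tg$gamma * grid
  sg <- sign(gval)
  sg[sg == 0] <- 1
  idx <- which(sg[-1] != sg[-length(sg)])
  if (length(idx) == 0) stop("no sign change found in the reduced flow")
  lo <- grid[idx]; hi <- grid[idx + 1]; flo <- gval[idx]
  n_iter <- ceiling(log2(max((hi - lo) / tol, 1))) + 2
  for (i in seq_len(n_iter)) {
    mid <- (lo + hi) / 2
    fmid <- toggle_f(tg, mid) - tg$gamma * mid
    take_left <- (sign(fmid) == sign(flo)) & (fmid != 0)
    lo <- ifelse(take_left, mid, lo)
    flo <- ifelse(take_left, fmid, flo)
    hi <- ifelse(take_left, hi, mid)
  }
  roots <- (lo + hi) / 2
  stable <- sg[idx] > 0
  structure(list(
    fixed_points = data.frame(A = roots, stable = stable),
    n_stable = sum(stable),
    is_bistable = sum(stable) >= 2
  ), class = "stability_profile")
}

#' Synthesis rate of gene A placing a toggle fixed point at a target level
#'
#' For a target steady state `A_star`, the required maximum synthesis rate
#' is `k_A* = gamma * A_star / h(A_star)` where `h` is the fractional
#' activation `alpha_A + (1 - alpha_A) * K_A^n_A / (K_A^n_A + B*(A_star)^n_A)`.
#' `valid` requires `A_star` to be a stable fixed point of the resulting
#' toggle genotype.
#'
#' @param A_star Target steady state (proteins, > 0).
#' @param tg A [toggle_genotype()]; its `k_A` entry is ignored.
#' @return List with `k_star` and `valid`.
#' @export
toggle_solution_kA <- function(A_star, tg) {
  stopifnot(inherits(tg, "toggle_genotype"))
  if (A_star <= 0) stop("A_star must be positive")
  B <- toggle_repressor(tg, A_star)
  Kn <- tg$K_A^tg$n_A
  h <- tg$alpha_A + (1 - tg$alpha_A) * Kn / (Kn + B^tg$n_A)
  k_star <- tg$gamma * A_star / h
  tg2 <- tg
  tg2$k_A <- k_star
  prof <- toggle_stability_profile(tg2)
  fp <- prof$fixed_points
  j <- which.min(abs(fp$A - A_star))
  valid <- abs(fp$A[j] - A_star) <= 1e-3 * max(1, A_star) && fp$stable[j]
  list(k_star = k_star, valid = valid)
}
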