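# total-variation distance between two mass vectors (padded to equal length)
tv_dist <- function(p, q) {
  n <- max(length(p), length(q))
  length(p) <- n
  length(q) <- n
  p[is.na(p)] <- 0
  q[is.na(q)] <- 0
  0.5 * sum(abs(p - q))
}

# random genotype within the physiological bounds (log-uniform)
random_genotype <- function() {
  b <- genotype_bounds()
  lu <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  genotype(k = lu(c(1, 1e3)), n_H = lu(c(0.5, 16)), K_D = lu(b$K_D))
}

# brute-force fixed-point oracle: sign changes of f(A) - gamma*A on a dense
# uniform grid (resolution `res` proteins), independent of the package's
# bracketing + bisection path
scan_fixed_points <- function(g, res = 1e-3) {
  upper <- 1.05 * g$k / g$gamma
  grid <- seq(0, upper, by = res)
  val <- synthesis_rate(g, grid) - g$gamma * grid
  sg <- sign(val)
  sg[sg == 0] <- 1
  idx <- which(sg[-1] != sg[-length(sg)])
  data.frame(A = (grid[idx] + grid[idx + 1]) / 2, stable = sg[idx] > 0)
}
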