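#' Physiological bounds on the evolvable biophysical parameters
#'
#' Mutated parameters are constrained to a range typical for a bacterial
#' transcription factor: maximum synthesis rate `k` in \[1e-2, 1e3\]
#' proteins per unit time, Hill coefficient `n_H` in \[1e-2, 16\], and
#' dissociation constant `K_D` in \[1e-2, 120\] proteins.
#'
#' @return Named list with elements `k`, `n_H`, `K_D`, each `c(min, max)`.
#' @export
genotype_bounds <- function() {
  list(k = c(1e-2, 1e3), n_H = c(1e-2, 16), K_D = c(1e-2, 120))
}

#' Construct a genotype of the self-activating gene
#'
#' A genotype is the evolvable parameter triple of the autoregulatory
#' circuit -- maximum synthesis rate `k`, Hill coefficient `n_H` and
#' dissociation constant `K_D` -- together with the fixed basal synthesis
#' fraction `alpha` and degradation rate constant `gamma`. Time is measured
#' in units of the protein lifetime, so `gamma = 1` by default and rates are
#' per dimensionless time unit.
#'
#' @param k Maximum synthesis rate (proteins per unit time).
#' @param n_H Hill coefficient (dimensionless).
#' @param K_D Dissociation constant (proteins).
#' @param alpha Basal synthesis fraction, in (0, 1].
#' @param gamma Degradation rate constant (> 0).
#' @return Object of class `"genotype"`.
#' @examples
#' g <- genotype(k = 80, n_H = 1, K_D = 10)
#' synthesis_rate(g, 0)  # basal rate k * alpha = 20
#' @export
genotype <- function(k, n_H, K_D, alpha = 0.25, gamma = 1) {
  b <- genotype_bounds()
  stopifnot(is.numeric(k), is.numeric(n_H), is.numeric(K_D),
            length(k) == 1, length(n_H) == 1, length(K_D) == 1)
  if (k < b$k[1] || k > b$k[2])
    stop("k must lie within [", b$k[1], ", ", b$k[2], "]")
  if (n_H < b$n_H[1] || n_H > b$n_H[2])
    stop("n_H must lie within [", b$n_H[1], ", ", b$n_H[2], "]")
  if (K_D < b$K_D[1] || K_D > b$K_D[2])
    stop("K_D must lie within [", b$K_D[1], ", ", b$K_D[2], "]")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (gamma <= 0) stop("gamma must be positive")
  structure(list(k = k, n_H = n_H, K_D = K_D, alpha = alpha, gamma = gamma),
            class = "genotype")
}

#' @export
print.genotype <- function(x, ...) {
  cat(sprintf("<genotype> k = %.4g, n_H = %.4g, K_D = %.4g (alpha = %.3g, gamma = %.3g)\n",
              x$k, x$n_H, x$K_D, x$alpha, x$gamma))
  invisible(x)
}

#' Serialize a genotype to flat key-value entries
#'
#' @param g A `genotype`.
#' @return Named list with keys `k`, `nH`, `KD`, `alpha`, `gamma`.
#' @export
genotype_to_config <- function(g) {
  stopifnot(inherits(g, "genotype"))
  list(k = g$k, nH = g$n_H, KD = g$K_D, alpha = g$alpha, gamma = g$gamma)
}

#' Deserialize a genotype from flat key-value entries
#'
#' @param entries Named list with keys `k`, `nH`, `KD` and optionally
#'   `alpha`, `gamma`.
#' @return A `genotype`.
#' @export
genotype_from_config <- function(entries) {
  genotype(k = as.numeric(entries$k),
           n_H = as.numeric(entries$nH),
           K_D = as.numeric(entries$KD),
           alpha = if (is.null(entries$alpha)) 0.25 else as.numeric(entries$alpha),
           gamma = if (is.null(entries$gamma)) 1 else as.numeric(entries$gamma))
}

# clamp parameter vectors to the physiological range (used after mutation)
clamp_params <- function(k, n_H, K_D) {
  b <- genotype_bounds()
  list(k = pmin(pmax(k, b$k[1]), b$k[2]),
       n_H = pmin(pmax(n_H, b$n_H[1]), b$n_H[2]),
       K_D = pmin(pmax(K_D, b$K_D[1]), b$K_D[2]))
}
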