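#' Random draw parameterizing one mutation event
#'
#' The spherical mutation scheme draws a radius `r ~ U(0, 1)` and direction
#' angles `phi1 ~ U(-1, 1)`, `phi2 ~ U(0, 2*pi)`; the displacement in
#' log-base-M parameter space then has norm exactly `r` (so a single
#' mutation can move a genotype at most one `M`-fold step in any
#' direction).
#'
#' @param n Number of draws.
#' @return data.frame with columns `r`, `phi1`, `phi2`.
#' @export
mutation_draw <- function(n = 1) {
  data.frame(r = stats::runif(n),
             phi1 = stats::runif(n, -1, 1),
             phi2 = stats::runif(n, 0, 2 * pi))
}

# exponents of M for each scheme; draws is a data.frame whose columns
# depend on the scheme. Returns matrix with columns ek, en, eK.
mutation_exponents <- function(scheme, n) {
  switch(scheme,
    spherical = {
      d <- mutation_draw(n)
      s <- sqrt(1 - d$phi1^2)
      cbind(ek = d$r * s * cos(d$phi2),
            en = d$r * s * sin(d$phi2),
            eK = d$r * d$phi1)
    },
    homogeneous_spherical = {
      d <- mutation_draw(n)
      r <- d$r^(1 / 3)  # uniform density in the log-space ball
      s <- sqrt(1 - d$phi1^2)
      cbind(ek = r * s * cos(d$phi2),
            en = r * s * sin(d$phi2),
            eK = r * d$phi1)
    },
    cubic = cbind(ek = stats::runif(n, -1, 1),
                  en = stats::runif(n, -1, 1),
                  eK = stats::runif(n, -1, 1)),
    `1d` = {
      which_p <- sample.int(3L, n, replace = TRUE)
      e <- stats::runif(n, -1, 1)
      m <- matrix(0, n, 3, dimnames = list(NULL, c("ek", "en", "eK")))
      m[cbind(seq_len(n), which_p)] <- e
      m
    },
    stop("unknown mutation scheme: ", scheme)
  )
}

#' Mutate a genotype multiplicatively
#'
#' Applies one multiplicative mutation: each evolvable parameter is
#' multiplied by `M` raised to a random exponent. The default spherical
#' scheme uses
#' `k' = k * M^(r * sqrt(1 - phi1^2) * cos(phi2))`,
#' `n_H' = n_H * M^(r * sqrt(1 - phi1^2) * sin(phi2))`,
#' `K_D' = K_D * M^(r * phi1)`,
#' so the log-M displacement norm equals `r <= 1`. Variants:
#' `homogeneous_spherical` replaces `r` by `r^(1/3)` (uniform density in
#' the ball), `cubic` uses three independent `U(-1, 1)` exponents, and
#' `1d` mutates a single uniformly chosen parameter. Results are clamped
#' to the physiological bounds ([genotype_bounds()]).
#'
#' @param g A [genotype()].
#' @param M Mutation step-size (maximum fold change, > 1).
#' @param scheme Mutation scheme.
#' @param draw Optional pre-made draw (data.frame row with `r`, `phi1`,
#'   `phi2`; spherical schemes only) for reproducible single steps.
#' @return List with the mutated `genotype` and `mutated = TRUE`.
#' @export
mutate_genotype <- function(g, M,
                            scheme = c("spherical", "homogeneous_spherical",
                                       "cubic", "1d"),
                            draw = NULL) {
  stopifnot(inherits(g, "genotype"))
  scheme <- match.arg(scheme)
  if (M <= 1) stop("M must exceed 1")
  if (!is.null(draw)) {
    if (!scheme %in% c("spherical", "homogeneous_spherical"))
      stop("explicit draws apply to the spherical schemes only")
    r <- if (scheme == "spherical") draw$r else draw$r^(1 / 3)
    s <- sqrt(1 - draw$phi1^2)
    e <- c(ek = r * s * cos(draw$phi2), en = r * s * sin(draw$phi2),
           eK = r * draw$phi1)
  } else {
    e <- mutation_exponents(scheme, 1)[1, ]
  }
  p <- clamp_params(g$k * M^e[["ek"]], g$n_H * M^e[["en"]],
                    g$K_D * M^e[["eK"]])
  list(genotype = genotype(p$k, p$n_H, p$K_D, g$alpha, g$gamma),
       mutated = TRUE)
}

#' Select the next generation
#'
#' Default scheme is tournament selection: for each of `N` offspring slots,
#' `s_t` distinct cells are sampled uniformly from the population and the
#' one with the highest fitness is cloned (ties broken uniformly at
#' random); tournaments are independent, with replacement across slots.
#' `s_t = 1` is pure drift; `s_t = N` clones only the fittest cell.
#' Alternatives: `truncation` draws parents uniformly from the top
#' `ceiling(N / s_t)` cells by fitness; `proportional` draws parents with
#' probability proportional to fitness.
#'
#' @param fitness Numeric fitness vector of the current population.
#' @param s_t Tournament size (or truncation pressure), in `[1, N]`.
#' @param scheme `"tournament"`, `"truncation"` or `"proportional"`.
#' @param n_offspring Number of offspring (default `length(fitness)`).
#' @return Integer vector of parent indices (length `n_offspring`).
#' @export
select_next_generation <- function(fitness, s_t,
                                   scheme = c("tournament", "truncation",
                                              "proportional"),
                                   n_offspring = length(fitness)) {
  scheme <- match.arg(scheme)
  N <- length(fitness)
  if (s_t < 1 || s_t > N) stop("s_t must lie in [1, N]")
  switch(scheme,
    tournament = {
      if (s_t == 1) return(sample.int(N, n_offspring, replace = TRUE))
      vapply(seq_len(n_offspring), function(i) {
        cohort <- sample.int(N, s_t)  # distinct cells within a tournament
        f <- fitness[cohort]
        best <- which(f == max(f))
        if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
        cohort[best]
      }, integer(1))
    },
    truncation = {
      n_top <- ceiling(N / s_t)
      top <- order(fitness, decreasing = TRUE)[seq_len(n_top)]
      top[sample.int(n_top, n_offspring, replace = TRUE)]
    },
    proportional = {
      if (all(fitness <= 0)) stop("proportional selection needs positive fitness")
      sample.int(N, n_offspring, replace = TRUE, prob = fitness / sum(fitness))
    }
  )
}
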