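test_that("synthesis rate follows the Hill form with basal floor and saturation", {
  g <- genotype(k = 80, n_H = 1, K_D = 10)
  expect_equal(synthesis_rate(g, 0), 20)                     # k * alpha
  g16 <- genotype(k = 80, n_H = 16, K_D = 50)
  expect_equal(synthesis_rate(g16, 50), 50)                  # half activation at K_D
  expect_equal(synthesis_rate(g16, 1e6), 80, tolerance = 1e-6)
  A <- seq(0, 200, length.out = 500)
  f <- synthesis_rate(g16, A)
  expect_true(all(diff(f) >= 0))
  expect_true(all(f >= 20 - 1e-12 & f <= 80 + 1e-12))
  expect_error(synthesis_rate(g, -1), "non-negative")
})

test_that("fixed points match closed-form and dense-scan oracles", {
  # n_H = 1 reduces to a quadratic: A^2 - 70 A - 200 = 0
  prof <- stability_profile(genotype(80, 1, 10))
  expect_equal(nrow(prof$fixed_points), 1L)
  expect_true(prof$fixed_points$stable)
  expect_equal(prof$fixed_points$A, (70 + sqrt(5700)) / 2, tolerance = 1e-6)
  expect_false(prof$is_bistable)

  # K_D > k limit: monostable LOW at alpha * k
  prof2 <- stability_profile(genotype(80, 16, 120))
  expect_equal(prof2$n_stable, 1L)
  expect_equal(prof2$fixed_points$A[1], 20, tolerance = 1e-3)

  # random genotypes against the brute-force scan
  set.seed(101)
  for (i in 1:40) {
    g <- random_genotype()
    prof <- stability_profile(g)
    ref <- scan_fixed_points(g)
    expect_equal(nrow(prof$fixed_points), nrow(ref))
    expect_equal(prof$fixed_points$A, ref$A, tolerance = 2e-3)
    expect_equal(prof$fixed_points$stable, ref$stable)
  }
})

test_that("stability profiles alternate and bound stable points at the ends", {
  set.seed(202)
  for (i in 1:40) {
    g <- random_genotype()
    fp <- stability_profile(g)$fixed_points
    expect_true(all(diff(fp$A) > 0))
    expect_true(fp$stable[1])
    expect_true(fp$stable[nrow(fp)])
    if (nrow(fp) > 1)
      expect_true(all(fp$stable == rep(c(TRUE, FALSE), length.out = nrow(fp))))
    expect_true(nrow(fp) %% 2 == 1)
    expect_lte(nrow(fp), 3)
  }
})

test_that("sharp-activation limit is bistable exactly between alpha*k and k", {
  # n_H = 16 proxies the step-function limit with k = 80, alpha = 0.25:
  # bistable for K_D well inside (20, 80), monostable beyond a 10% band
  for (KD in c(30, 40, 50, 60))
    expect_true(stability_profile(genotype(80, 16, KD))$is_bistable)
  for (KD in c(10, 17.9))
    expect_false(stability_profile(genotype(80, 16, KD))$is_bistable)
  for (KD in c(88.1, 110))
    expect_false(stability_profile(genotype(80, 16, KD))$is_bistable)
})

test_that("solution synthesis rate places (and certifies) the target fixed point", {
  # saturated-activation limit: K_D -> 0 gives k* = gamma * A*
  expect_equal(solution_k(20, 16, 0.01)$k_star, 20, tolerance = 1e-9)
  # direct arithmetic for n_H = 1
  s <- solution_k(80, 1, 10)
  expect_equal(s$k_star, 80 * 90 / 82.5, tolerance = 1e-12)
  expect_true(s$valid)
  prof <- stability_profile(genotype(s$k_star, 1, 10))
  expect_true(any(abs(prof$fixed_points$A - 80) < 1e-5))

  # the bistable hub: one genotype solves both optima
  sL <- solution_k(20, 16, 50)
  sH <- solution_k(80, 16, 50)
  expect_true(sL$valid && sH$valid)
  expect_equal(sL$k_star, 80, tolerance = 1e-3)
  expect_equal(sH$k_star, sL$k_star, tolerance = 1e-3)

  # the Eq-8 fixed point at K_D near A* is unstable -> not a solution
  expect_false(solution_k(20, 16, 20)$valid)

  expect_error(solution_k(0, 2, 10), "positive")
  expect_error(solution_k(-5, 2, 10), "positive")
})

test_that("solution_k then stability_profile always recovers the target", {
  set.seed(303)
  for (i in 1:40) {
    n_H <- exp(stats::runif(1, log(1), log(16)))
    K_D <- exp(stats::runif(1, log(1), log(120)))
    A_star <- sample(c(20, 80), 1)
    s <- solution_k(A_star, n_H, K_D)
    if (s$k_star < 1e-2 || s$k_star > 1e3) next
    fp <- stability_profile(genotype(s$k_star, n_H, K_D))$fixed_points
    expect_true(min(abs(fp$A - A_star)) < 1e-4)
  }
})

test_that("genotype construction enforces the physiological ranges", {
  expect_error(genotype(1e4, 2, 10), "k must lie")
  expect_error(genotype(80, 20, 10), "n_H must lie")
  expect_error(genotype(80, 2, 500), "K_D must lie")
  expect_error(genotype(80, 2, 10, alpha = 0), "alpha")
  expect_error(genotype(80, 2, 10, gamma = -1), "gamma")
  g <- genotype(80, 2, 10)
  expect_identical(genotype_from_config(genotype_to_config(g)), g)
})

test_that("toggle switch reduction reproduces the quasi-steady repressor and bistability", {
  tg <- toggle_genotype(k_A = 1, n_A = 16, K_A = 12)
  # at A = K_B the repression Hill term is 1/2: B* = 50 * (0.2 + 0.8/2)
  expect_equal(epievolve:::toggle_repressor(tg, 20), 30)

  solL <- toggle_solution_kA(20, tg)
  solH <- toggle_solution_kA(80, tg)
  expect_true(solL$valid && solH$valid)
  # both solution rates are reported; at {n_A = 16, K_A = 12} they are close
  # (no asserted tolerance - the approximation quality is checked loosely)
  expect_lt(abs(log(solL$k_star / solH$k_star)), 0.25)
  tgB <- tg
  tgB$k_A <- solL$k_star
  expect_true(toggle_stability_profile(tgB)$is_bistable)

  tg1 <- toggle_genotype(k_A = 1, n_A = 1, K_A = 1)
  sol1 <- toggle_solution_kA(20, tg1)
  tg1$k_A <- sol1$k_star
  expect_false(toggle_stability_profile(tg1)$is_bistable)

  expect_error(toggle_solution_kA(-1, tg), "positive")
  expect_error(toggle_genotype(k_A = -1, n_A = 2, K_A = 10), "positive")
})
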