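test_that("the truncated generator has the stated tridiagonal structure", {
  g <- genotype(80, 1, 10)
  gen <- build_generator(g, 1)
  B <- as.matrix(gen)
  f0 <- synthesis_rate(g, 0)
  f1 <- synthesis_rate(g, 1)
  # the birth transition out of the top state is dropped but its rate stays
  # on the diagonal (absorbing truncation)
  expect_equal(B, matrix(c(-f0, f0, 1, -1 - f1), 2, 2), tolerance = 1e-12)

  gen2 <- build_generator(g, 200)
  B2 <- as.matrix(gen2)
  cs <- colSums(B2)
  expect_equal(cs[1:200], rep(0, 200), tolerance = 1e-10)  # interior conservation
  expect_lt(cs[201], 0)                                    # boundary leaks
  expect_error(build_generator(g, 0))
})

test_that("the product-form stationary law annihilates the generator", {
  set.seed(21)
  for (i in 1:5) {
    g <- random_genotype()
    pi_ <- stationary_distribution(g)
    if (pi_$probs[pi_$A_max + 1] > 1e-12) next  # needs negligible boundary mass
    B <- as.matrix(build_generator(g, pi_$A_max))
    expect_lt(max(abs(B %*% pi_$probs)), 1e-10)
  }
  # alpha = 1: closed-form Poisson
  gp <- genotype(20, 1, 10, alpha = 1)
  pi_p <- stationary_distribution(gp)
  expect_equal(pi_p$probs, dpois(0:pi_p$A_max, 20), tolerance = 1e-12)
  expect_equal(sum(pi_p$probs), 1)
})

test_that("FSP propagation is the identity at tau = 0 and converges to stationarity", {
  g <- genotype(50, 2, 30)
  pi_ <- stationary_distribution(g)
  gen <- build_generator(g, pi_$A_max)
  rho0 <- epievolve:::point_mass(50, pi_$A_max)
  expect_equal(propagate_fsp(gen, rho0, 0)$probs, rho0$probs)

  d <- propagate_fsp(gen, rho0, 60)
  expect_lt(tv_dist(d$probs, pi_$probs), 1e-6)
  expect_true(all(d$probs >= 0))

  # alpha = 1 from an empty cell: exact Poisson at long times
  gp <- genotype(20, 1, 10, alpha = 1)
  dp <- epievolve:::propagate_point(gp, 0, 30)
  expect_lt(tv_dist(dp$probs, dpois(0:dp$A_max, 20)), 1e-9)
})

test_that("an insufficient truncation is reported as leak", {
  g <- genotype(200, 1, 10)
  gen <- build_generator(g, 60)  # far below the stationary mean ~ 200
  rho0 <- epievolve:::point_mass(60, 60)
  expect_error(propagate_fsp(gen, rho0, 4, max_leak = 1e-8), "truncation")
  d <- propagate_fsp(gen, rho0, 4)
  expect_gt(d$leak, 1e-8)
  # the auto-doubling wrapper reaches the required tolerance even at k = 200
  d2 <- epievolve:::propagate_point(g, 60, 4)
  expect_lte(d2$leak, 1e-8)
})

test_that("FSP transients agree with SSA Monte-Carlo at the working life span", {
  sk <- solution_k(20, 16, 50)
  g <- genotype(sk$k_star, 16, 50)
  fsp <- epievolve:::propagate_point(g, 20, 4)
  set.seed(22)
  emp <- empirical_distribution(g, 20, 4, n_reps = 2e4, A_max = fsp$A_max)
  expect_lt(tv_dist(emp$probs, fsp$probs), 0.02)
})

test_that("noise load is the complement of expected fitness and vanishes for flat fitness", {
  sk <- solution_k(80, 16, 50)
  g <- genotype(sk$k_star, 16, 50)
  nl <- noise_load(g, "HIGH")
  expect_equal(nl$noise_load, 1 - nl$expected_fitness)
  expect_true(nl$noise_load >= 0 && nl$noise_load <= 1)
  flat <- noise_load(g, "HIGH", fitness = function(a) rep(1, length(a)))
  expect_equal(flat$noise_load, 0, tolerance = 1e-8)

  # Monte-Carlo estimate agrees within 3 standard errors
  set.seed(23)
  n <- 2e4
  emp <- empirical_distribution(g, 80, 4, n_reps = n)
  om <- fitness_score(0:emp$A_max, "HIGH")
  w_mc <- sum(om * emp$probs)
  se <- sqrt(sum(om^2 * emp$probs) - w_mc^2) / sqrt(n)
  expect_lt(abs(w_mc - nl$expected_fitness), 3 * se + 1e-4)
})

test_that("epimutation probabilities behave like switching probabilities", {
  # strongly monostable HIGH genotype: essentially no HIGH -> LOW switching
  sH <- solution_k(80, 1, 0.5)
  gH <- genotype(sH$k_star, 1, 0.5)
  p <- epimutation_probability(gH, "HIGH", "LOW")
  expect_gte(p, 0)
  expect_lt(p, 1e-4)
  expect_error(epimutation_probability(gH, "HIGH", "HIGH"), "differ")

  # stronger memory at higher nonlinearity: at K_D = 50 the minimum two-way
  # switching probability decreases from n_H = 8 to n_H = 16
  two_way_min <- function(n_H) {
    gL <- genotype(solution_k(20, n_H, 50)$k_star, n_H, 50)
    gHh <- genotype(solution_k(80, n_H, 50)$k_star, n_H, 50)
    min(epimutation_probability(gL, "LOW", "HIGH"),
        epimutation_probability(gHh, "HIGH", "LOW"))
  }
  expect_lt(two_way_min(16), two_way_min(8))
})

test_that("higher nonlinearity lowers the worst-case noise load in the bistable band", {
  worst <- function(n_H, K_D) {
    max(noise_load(genotype(solution_k(20, n_H, K_D)$k_star, n_H, K_D),
                   "LOW")$noise_load,
        noise_load(genotype(solution_k(80, n_H, K_D)$k_star, n_H, K_D),
                   "HIGH")$noise_load)
  }
  expect_lt(worst(16, 50), worst(4, 50))
})
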