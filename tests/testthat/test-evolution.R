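test_that("the Lorentzian fitness matches its worked values and alternative shapes are width-matched", {
  expect_equal(fitness_score(80, "HIGH"), 1)
  expect_equal(fitness_score(84, "HIGH"), 0.5)   # eps^2 = 16, deviation 4
  expect_equal(fitness_score(80, "LOW"), 4 / 3604)
  expect_equal(fitness_score(20, "LOW"), 1)

  # gaussian matched at full width at half maximum: 0.5 at deviation eps
  expect_equal(fitness_score(84, "HIGH", shape = "gaussian"), 0.5)
  expect_equal(fitness_score(80, "HIGH", shape = "gaussian"), 1)
  # step: 1 within twice the half-width, floor outside
  expect_equal(fitness_score(88, "HIGH", shape = "step"), 1)
  expect_equal(fitness_score(89, "HIGH", shape = "step"), 1e-6)
})

test_that("spherical mutation moves genotypes by exactly r in log-M units", {
  g <- genotype(80, 2, 10)
  still <- mutate_genotype(g, M = 1.5, draw = list(r = 0, phi1 = 0.3, phi2 = 1))
  expect_equal(still$genotype$k, g$k)
  expect_equal(still$genotype$n_H, g$n_H)
  expect_equal(still$genotype$K_D, g$K_D)

  only_KD <- mutate_genotype(g, M = 1.5,
                             draw = list(r = 0.7, phi1 = 1, phi2 = 2))
  expect_equal(only_KD$genotype$k, g$k)
  expect_equal(only_KD$genotype$n_H, g$n_H)
  expect_equal(only_KD$genotype$K_D, g$K_D * 1.5^0.7)

  set.seed(41)
  e <- epievolve:::mutation_exponents("spherical", 1e4)
  norms <- sqrt(rowSums(e^2))
  d <- epievolve:::mutation_draw  # draws above consumed r, phi1, phi2 triples
  expect_true(all(norms <= 1))
  # the log-M displacement norm is exactly r ~ U(0, 1)
  expect_gt(stats::ks.test(norms, "punif")$p.value, 0.01)

  # homogeneous variant: norms are r^(1/3), i.e. P(norm <= x) = x^3
  set.seed(42)
  eh <- epievolve:::mutation_exponents("homogeneous_spherical", 1e4)
  nh <- sqrt(rowSums(eh^2))
  expect_gt(stats::ks.test(nh^3, "punif")$p.value, 0.01)

  # 1d variant touches exactly one coordinate
  e1 <- epievolve:::mutation_exponents("1d", 500)
  expect_true(all(rowSums(e1 != 0) <= 1))
  expect_error(mutate_genotype(g, M = 0.9), "exceed 1")
})

test_that("mutation clamps every parameter to the physiological range", {
  set.seed(43)
  g <- genotype(999, 15.9, 119)
  b <- genotype_bounds()
  for (i in 1:200) {
    g2 <- mutate_genotype(g, M = 5)$genotype
    expect_true(g2$k >= b$k[1] && g2$k <= b$k[2])
    expect_true(g2$n_H >= b$n_H[1] && g2$n_H <= b$n_H[2])
    expect_true(g2$K_D >= b$K_D[1] && g2$K_D <= b$K_D[2])
  }
})

test_that("tournament selection spans drift to elitism", {
  fit <- c(1.0, 0.1)
  set.seed(44)
  # N = 2, s_t = 2: every tournament contains both cells, the fitter wins
  expect_true(all(select_next_generation(fit, s_t = 2) == 1L))

  fit10 <- seq(0.1, 1, length.out = 10)
  expect_true(all(select_next_generation(fit10, s_t = 10) == 10L))

  # s_t = 1 is uniform drift
  sel <- select_next_generation(rep(0.5, 4), s_t = 1, n_offspring = 8000)
  expect_gt(stats::chisq.test(table(factor(sel, levels = 1:4)))$p.value, 0.001)

  # selected mean fitness is non-decreasing in s_t
  set.seed(45)
  fitN <- stats::runif(100)
  means <- vapply(c(1, 2, 5, 20, 100), function(s)
    mean(fitN[select_next_generation(fitN, s, n_offspring = 4000)]), numeric(1))
  expect_true(all(diff(means) >= -0.02))

  expect_error(select_next_generation(fit10, s_t = 11), "s_t")

  # truncation keeps the top cells; proportional follows fitness weights
  selt <- select_next_generation(fit10, s_t = 5, scheme = "truncation",
                                 n_offspring = 300)
  expect_true(all(fit10[selt] >= sort(fit10, decreasing = TRUE)[2]))
  selp <- select_next_generation(c(1, 0), s_t = 1, scheme = "proportional",
                                 n_offspring = 50)
  expect_true(all(selp == 1L))
})

test_that("environment schedules produce the stated epochs and cycles", {
  s <- env_schedule(nu = 0.1)
  out <- schedule_environments(s, 10000)
  expect_identical(out$n_cycles, 500L)
  expect_identical(out$env[1:10], rep("LOW", 10))
  expect_identical(out$env[11:20], rep("HIGH", 10))
  expect_identical(environment_at(s, 11), "HIGH")

  expect_identical(schedule_environments(env_schedule(0.01), 300)$env[1:100],
                   rep("LOW", 100))
  expect_error(env_schedule(nu = 0.3), "integer epoch")
  expect_error(env_schedule(nu = 0), "nu")

  set.seed(46)
  st <- schedule_environments(env_schedule(0.1, mode = "stochastic"), 1e5)
  # epoch lengths are geometric(nu): mean within 3 standard errors of 10
  lens <- rle(st$env)$lengths
  n <- length(lens)
  expect_lt(abs(mean(lens) - 10), 3 * sqrt(90) / sqrt(n) + 0.2)
})

test_that("CONTROL phenotypes are hysteretic basin lookups", {
  g1 <- genotype(80, 1, 10)
  expect_equal(control_phenotype(g1, c(0, 50, 500)),
               rep((70 + sqrt(5700)) / 2, 3), tolerance = 1e-5)

  sk <- solution_k(20, 16, 50)
  gB <- genotype(sk$k_star, 16, 50)
  prof <- stability_profile(gB)
  u <- prof$fixed_points$A[!prof$fixed_points$stable]
  expect_equal(control_phenotype(gB, 30), 20, tolerance = 1e-3)
  expect_equal(control_phenotype(gB, 60), 80, tolerance = 0.05)
  # tie at the unstable point resolves to the lower stable state
  expect_equal(control_phenotype(gB, u), 20, tolerance = 1e-3)
  expect_error(control_phenotype(gB, -1), "non-negative")
})

test_that("cycle summaries are geometric means", {
  expect_equal(cycle_summary(rep(1, 6))$W_cycle, 1)
  expect_equal(cycle_summary(rep(0.37, 8))$W_cycle, 0.37)
  expect_equal(cycle_summary(c(0.25, 1, 1, 1))$W_cycle, 0.25^0.25)
  expect_equal(cycle_summary(c(0.25, 1, 1, 1))$prod_w, 0.25)
  expect_error(cycle_summary(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("evolutionary runs are reproducible and respect their invariants", {
  cfg <- evolution_config(N = 60, st = 6, generations = 80, seed = 99)
  r1 <- run_evolution(cfg)
  r2 <- run_evolution(cfg)
  expect_identical(r1$generations, r2$generations)
  expect_identical(r1$lineages, r2$lineages)
  expect_true(all(r1$generations$w >= 0 & r1$generations$w <= 1))
  expect_true(all(r1$generations$f_B >= 0 & r1$generations$f_B <= 1))
  expect_identical(nrow(r1$cycles), 4L)

  # no mutation: the founder genotype is the only one ever seen
  r0 <- run_evolution(evolution_config(N = 40, st = 1, u = 0, generations = 60,
                                       seed = 3))
  expect_identical(r0$n_genotypes, 1L)

  out <- tempfile()
  paths <- write_run(r1, out)
  expect_true(all(file.exists(paths)))
  gens <- utils::read.csv(file.path(out, "generations.csv"))
  expect_equal(nrow(gens), 80L)
})

test_that("configuration validation catches out-of-range settings", {
  expect_error(evolution_config(N = 1), "N must")
  expect_error(evolution_config(st = 900), "st must")
  expect_error(evolution_config(M = 0.9), "M must exceed 1")
  expect_error(evolution_config(nu = 0.3), "integer epoch")
  expect_error(evolution_config(u = 1.5), "u must")
  expect_error(evolution_config(selection = "rank"), "selection")
})
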