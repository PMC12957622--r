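test_that("the simulator preserves marginal distributions exactly", {
  # one rater per simulated matrix: a rater's ratings are iid from the
  # configured marginal for every rho, so the chi-square reference is
  # exactly calibrated (raters within one matrix share latent draws and
  # would give correlated, variance-inflated tests)
  set.seed(21)
  for (marg in c("uniform", "skew_low", "skew_high")) {
    for (rho in c(0.3, 0.9)) {
      p <- marginal_probs(marg, 7)
      counts <- dentagree:::simulate_rating_counts(5000, 3, p, rho)
      obs <- tabulate(attr(counts, "values")[, 1], 7)
      gof <- suppressWarnings(stats::chisq.test(obs, p = p))
      expect_gt(gof$p.value, 0.001)
    }
  }
  expect_error(marginal_probs(c(0.5, 0.6), 2), "sum to 1")
})

test_that("rho = 1 copies the latent stage for every rater", {
  for (i in 1:5) {
    m <- simulate_ratings(sim_design(20, 9, 8, "uniform", rho = 1,
                                     seed = i))
    expect_true(all(m$values == m$values[, 1]))
    expect_equal(gwet_ac(m)$coefficient, 1)
  }
})

test_that("at rho = 0 mean AC1 is at chance level", {
  set.seed(22)
  p <- marginal_probs("uniform", 5)
  vals <- replicate(400, {
    cc <- dentagree:::simulate_rating_counts(200, 9, p, 0)
    dentagree:::agreement_from_counts(cc, diag(5), "gwet")$coefficient
  })
  expect_lt(abs(mean(vals)), 0.03)
})

test_that("calibration recovers the analytic rho under uniform marginals", {
  d <- sim_design(200, 9, 5, "uniform")
  rho <- calibrate_rho(0.6, d, "identity", reps = 300, seed = 14)
  expect_equal(rho, sqrt(0.6), tolerance = 0.03)
  # self-consistency across independent seeds, ordinal weights, skew
  d2 <- sim_design(100, 9, 7, "skew_low")
  r1 <- calibrate_rho(0.6, d2, "ordinal", reps = 300, seed = 31)
  r2 <- calibrate_rho(0.6, d2, "ordinal", reps = 300, seed = 77)
  expect_equal(r1, r2, tolerance = 0.03)
  expect_error(calibrate_rho(0.005, sim_design(50, 9, 3, "uniform"),
                             "ordinal", reps = 200, seed = 3),
               "chance level")
  expect_error(calibrate_rho(-0.1, sim_design(50, 9, 3, "uniform")),
               "in \\(0, 1\\)")
})

test_that("the one-sided AC2 test holds its size at the null", {
  d <- sim_design(100, 9, 7, "uniform")
  rho <- calibrate_rho(0.4, d, "ordinal", reps = 600, seed = 4)
  pw <- estimate_power(sim_design(100, 9, 7, "uniform", rho = rho),
                       null_value = 0.4, reps = 2000, seed = 8)
  expect_lt(abs(pw$power - 0.05), 2 * sqrt(0.05 * 0.95 / 2000) + 0.02)
})

test_that("power is monotone in sample size and saturates at rho = 1", {
  p10 <- estimate_power(sim_design(10, 9, 7, "uniform", rho = 0.775),
                        reps = 600, seed = 2)
  p40 <- estimate_power(sim_design(40, 9, 7, "uniform", rho = 0.775),
                        reps = 600, seed = 2)
  expect_gte(p40$power, p10$power - 0.02)
  pr1 <- estimate_power(sim_design(5, 9, 7, "uniform", rho = 1),
                        reps = 200, seed = 3)
  expect_equal(pr1$power, 1)
})

test_that("Bonett's ICC precision formula matches its worked values", {
  expect_identical(bonett_icc_n(0.8, 9, 0.1, 0.95), 25L)
  expect_identical(bonett_icc_n(0.8, 9, 0.05, 0.95), 95L)
  expect_lte(bonett_icc_n(0.8, 9, 0.2, 0.95), bonett_icc_n(0.8, 9, 0.1,
                                                           0.95))
  expect_error(bonett_icc_n(1.2, 9, 0.1), "rho_plan")
  expect_error(bonett_icc_n(0.8, 1, 0.1), "k_raters")
})

test_that("the minimum-n search is reproducible and returns a grid", {
  pg1 <- min_n_for_power(categories = 7L, marginals = "uniform",
                         n_grid = c(5L, 10L, 15L), reps = 200,
                         calib_reps = 150, seed = 17)
  pg2 <- min_n_for_power(categories = 7L, marginals = "uniform",
                         n_grid = c(5L, 10L, 15L), reps = 200,
                         calib_reps = 150, seed = 17)
  expect_identical(pg1$grid, pg2$grid)
  expect_identical(pg1$min_n, pg2$min_n)
  expect_true(all(pg1$grid$power >= 0 & pg1$grid$power <= 1))
  # target power 0: the first grid point suffices
  pg0 <- min_n_for_power(categories = 7L, marginals = "uniform",
                         n_grid = c(5L, 10L), target_power = 0,
                         reps = 100, calib_reps = 100, seed = 17)
  expect_equal(pg0$recommended_n, 5L)
})

test_that("precision-based sample size shrinks as the CI demand loosens", {
  loose <- precision_n_simulated("ac2", 0.8, 0.5, n_raters = 6,
                                 n_categories = 5,
                                 n_grid = c(10L, 20L, 40L), reps = 100,
                                 seed = 19)
  expect_equal(loose$n, 10L)
  tight <- precision_n_simulated("ac2", 0.8, 0.08, n_raters = 6,
                                 n_categories = 5,
                                 n_grid = c(10L, 20L, 40L, 80L, 160L),
                                 reps = 100, seed = 19)
  expect_gte(tight$n, loose$n)
  kap <- precision_n_simulated("kappa", 0.8, 0.1, n_raters = 6,
                               n_categories = 5,
                               n_grid = c(10L, 20L, 40L, 80L),
                               reps = 100, seed = 23)
  expect_true(is.finite(kap$n))
})
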