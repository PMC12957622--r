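two_rater <- function(x, y, cats = sort(unique(c(x, y)))) {
  matrix_for(cbind(x, y), cats)
}

test_that("percent agreement enumerates weighted rater pairs", {
  m <- two_rater(c("A", "A", "B", "A"), c("A", "A", "B", "B"))
  expect_equal(percent_agreement(m), 0.75)
  expect_equal(percent_agreement(two_rater(c("A", "A"), c("A", "A"),
                                           c("A", "B"))), 1)
  expect_equal(percent_agreement(two_rater("A", "B", c("A", "B"))), 0)
  allna <- matrix_for(matrix(NA_character_, 3, 2), c("A", "B"))
  expect_error(percent_agreement(allna), "all cells are NA")
})

test_that("weighted Cohen's kappa matches the contingency definition", {
  k <- cohen_kappa_weighted(cbind(c("A", "A", "B", "A"),
                                  c("A", "A", "B", "B")),
                            kind = "identity")
  expect_equal(k$coefficient, 0.5)
  expect_equal(k$pa, 0.75)
  expect_equal(k$pe, 0.5)

  # identical sessions: kappa 1.000 [1.000; 1.000] for any weights
  x <- sample(LETTERS[4:8], 30, replace = TRUE)
  for (kind in c("identity", "ordinal", "quadratic")) {
    k1 <- cohen_kappa_weighted(cbind(x, x), kind = kind)
    expect_equal(k1$coefficient, 1)
    expect_equal(k1$ci_low, 1)
    expect_equal(k1$ci_high, 1)
  }

  # both raters constant: chance agreement 1, flagged not silent
  kd <- cohen_kappa_weighted(cbind(rep("D", 5), rep("D", 5)))
  expect_true(kd$degenerate)
  expect_true(is.na(kd$coefficient))
})

test_that("the kappa paradox appears under dominant-category prevalence", {
  x <- c(rep("H", 18), "H", "G")
  y <- c(rep("H", 18), "G", "H")
  k <- cohen_kappa_weighted(cbind(x, y), kind = "identity")
  m <- two_rater(x, y, c("G", "H"))
  ac1 <- gwet_ac(m)
  fl <- fleiss_kappa(m)
  expect_equal(k$pa, 0.9)                        # raw agreement high
  expect_equal(k$coefficient, -1 / 19)           # kappa negative
  expect_equal(ac1$coefficient, (0.9 - 0.095) / (1 - 0.095))
  expect_lt(fl$coefficient, 0.1)                 # Fleiss collapses too
  expect_gt(ac1$coefficient - k$coefficient, 0.5)
})

test_that("Gwet's AC matches the hand-computed worked example", {
  m <- two_rater(c("A", "A", "B", "A"), c("A", "A", "B", "B"))
  ac <- gwet_ac(m)
  expect_equal(ac$pa, 0.75)
  expect_equal(ac$pe, 0.46875)
  expect_equal(ac$coefficient, 0.28125 / 0.53125)
  # perfect agreement with two observed categories
  perf <- two_rater(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(gwet_ac(perf)$coefficient, 1)
})

test_that("Fleiss' kappa behaves at its anchors", {
  perf <- matrix_for(matrix(rep(c("A", "B", "A", "C"), 3), 4, 3),
                     c("A", "B", "C"))
  expect_equal(fleiss_kappa(perf)$coefficient, 1)
  set.seed(42)
  big <- matrix_for(matrix(sample(LETTERS[1:4], 500 * 4, replace = TRUE),
                           500, 4), LETTERS[1:4])
  expect_lt(abs(fleiss_kappa(big)$coefficient), 0.05)
})

test_that("AC2 with identity weights equals AC1 on arbitrary matrices", {
  set.seed(7)
  for (i in 1:20) {
    vals <- random_rating_values(sample(4:12, 1), sample(2:6, 1),
                                 LETTERS[1:4])
    m <- matrix_for(vals, LETTERS[1:4])
    if (sum(rowSums(!is.na(vals)) >= 2) < 2) next
    cats <- observed_categories(m)
    if (length(cats) < 2) next
    a1 <- gwet_ac(m, build_weights(cats, "identity"))
    a2 <- gwet_ac(m, {
      w <- build_weights(cats, "ordinal")
      w[] <- diag(length(cats)); w
    })
    expect_equal(a1$coefficient, a2$coefficient, tolerance = 1e-12)
  }
})

test_that("coefficients are invariant to rater and unit permutations", {
  set.seed(123)
  vals <- random_rating_values(10, 4, LETTERS[1:3])
  m <- matrix_for(vals, LETTERS[1:3])
  w <- build_weights(observed_categories(m), "ordinal")
  base <- gwet_ac(m, w)
  for (i in 1:5) {
    perm <- vals[sample(nrow(vals)), sample(ncol(vals))]
    mp <- matrix_for(perm, LETTERS[1:3])
    acp <- gwet_ac(mp, w)
    expect_equal(acp$coefficient, base$coefficient, tolerance = 1e-12)
    expect_equal(acp$se, base$se, tolerance = 1e-12)
    expect_equal(fleiss_kappa(mp)$coefficient,
                 fleiss_kappa(m)$coefficient, tolerance = 1e-12)
  }
})

test_that("estimates agree with brute-force formulas, with missing data", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(3:10, 1)
    r <- sample(2:5, 1)
    cats <- LETTERS[1:sample(2:4, 1)]
    vals <- random_rating_values(n, r, cats, na_frac = 0.15)
    if (sum(rowSums(!is.na(vals)) >= 2) < 2) next
    m <- matrix_for(vals, cats)
    seen <- observed_categories(m)
    if (length(seen) < 2) next
    w <- build_weights(seen, sample(c("identity", "ordinal",
                                      "quadratic"), 1))
    expect_equal(gwet_ac(m, w)$coefficient, bf_gwet(vals, w),
                 tolerance = 1e-12)
    expect_equal(fleiss_kappa(m)$coefficient, bf_fleiss(vals, seen),
                 tolerance = 1e-12)
  }
})

test_that("linearized SE tracks the jackknife on moderate samples", {
  set.seed(5)
  for (i in 1:4) {
    r <- sample(2:4, 1)
    cats <- as.character(1:4)
    vals <- matrix(as.character(attr(
      dentagree:::simulate_rating_counts(
        120, r, marginal_probs("skew_low", 4), 0.6), "values")),
      120, r)
    vals[sample(length(vals), 12)] <- NA
    m <- matrix_for(vals, cats)
    w <- build_weights(observed_categories(m), "ordinal")
    fit <- gwet_ac(m, w)
    expect_equal(fit$se, jackknife_se(vals, w), tolerance = 0.1)
  }
})

test_that("units with fewer than two ratings count as observations only", {
  vals <- rbind(c("A", "A", "A"),
                c("B", NA, NA),
                c("A", "B", NA))
  m <- matrix_for(vals, c("A", "B"))
  w <- build_weights(c("A", "B"), "identity")
  ac <- gwet_ac(m, w)
  expect_equal(ac$n_observations, 6L)
  expect_equal(ac$n_units, 3L)
  # pa over the two units with >= 2 ratings: (1 + 0) / 2
  expect_equal(ac$pa, 0.5)
})

test_that("benchmark scales bin coefficients as published", {
  expect_equal(benchmark_label(0.918, "landis_koch"), "almost perfect")
  expect_equal(benchmark_label(0.45, "landis_koch"), "moderate")
  expect_equal(benchmark_label(-0.1, "landis_koch"), "poor")
  expect_equal(benchmark_label(c(0.1, 0.3, 0.7), "landis_koch"),
               c("slight", "fair", "substantial"))
  expect_equal(benchmark_label(0.986, "portney_watkins"), "excellent")
  expect_equal(benchmark_label(c(0.4, 0.6, 0.8), "portney_watkins"),
               c("poor", "moderate", "good"))
})
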