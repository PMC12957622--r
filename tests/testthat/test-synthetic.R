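test_that("the generated study has the full two-session design", {
  study <- generate_study(study_config(seed = 5))
  tab <- study$ratings
  counts <- table(tab$method)
  expect_equal(unname(counts[["DEM"]]), 3600L)  # 50 x 4 x 9 x 2
  expect_equal(unname(counts[["GHK"]]), 3600L)
  expect_equal(unname(counts[["KUL"]]), 1800L)  # mandibular only
  expect_equal(unname(counts[["I3M"]]), 1800L)
  expect_equal(nrow(study$subjects), 50L)
  expect_true(all(study$subjects$chronological_age >= 14 &
                    study$subjects$chronological_age < 24))
  expect_equal(sort(unique(study$subjects$sex)), c("female", "male"))
})

test_that("zero NA rate produces a complete table", {
  cfg <- study_config(seed = 2)
  cfg$na_rate <- lapply(cfg$na_rate, function(v) v * 0)
  study <- generate_study(cfg)
  expect_equal(sum(is.na(study$ratings$value)), 0L)
})

test_that("the same seed reproduces a byte-identical ratings file", {
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_ratings(generate_study(study_config(seed = 11))$ratings, f1)
  write_ratings(generate_study(study_config(seed = 11))$ratings, f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_ratings(generate_study(study_config(seed = 12))$ratings, f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("session-1 stage frequencies match the configured marginals", {
  # a single observer's column is iid from the configured marginal (the
  # pooled 450 cells share 50 latent stages across 9 observers, so a
  # binomial-reference test there would be variance-inflated); the
  # Monte Carlo p-value handles the sparse stage C
  study <- generate_study(study_config(seed = 31))
  cfg <- study$truth$config
  tab <- study$ratings
  probs <- cfg$stage_marginals$DEM$`18`
  seen <- probs > 0
  expect_equal(sum(!seen), 3L)   # stages A-C carry no mass for 18
  for (obs_id in c(2L, 7L)) {
    v <- tab$value[tab$method == "DEM" & tab$tooth == 18L &
                     tab$session == 1L & tab$observer_id == obs_id]
    v <- v[!is.na(v)]
    cnt <- as.integer(table(factor(v, names(probs)[seen])))
    set.seed(1000 + obs_id)
    gof <- suppressWarnings(
      stats::chisq.test(cnt, p = probs[seen] / sum(probs[seen]),
                        simulate.p.value = TRUE, B = 5000))
    expect_gt(gof$p.value, 0.001)
  }
  # no observer ever uses a zero-probability stage
  all18 <- tab$value[tab$method == "DEM" & tab$tooth == 18L]
  expect_false(any(all18 %in% c("A", "B", "C")))
})

test_that("perfect-repeat sessions give intra-observer kappa 1", {
  cfg <- study_config(seed = 13, intra_repeat_agreement = 1)
  study <- generate_study(cfg)
  for (obs in c(1L, 5L, 9L)) {
    pr <- session_pairs(study$ratings, obs, "DEM", 38L)
    k <- cohen_kappa_weighted(pr[pr$complete, ],
                              scheme_categories = LETTERS[1:8])
    expect_equal(k$coefficient, 1)
  }
})

test_that("the pipeline recovers the generating parameters", {
  study <- generate_study(study_config(seed = 41))
  rec <- recover_parameters(study)
  icc_rows <- grepl("ICC", rec$quantity)
  expect_true(all(abs(rec$estimate[icc_rows] -
                        rec$reference[icc_rows]) < 0.03))
  intra <- grepl("intra", rec$quantity)
  expect_true(all(rec$estimate[intra] >=
                    study$truth$config$intra_repeat_agreement - 0.03))
})

test_that("NA prevalence flag follows the configured rates", {
  # defaults keep KUL NA rates far below 5%: no flag expected
  study <- generate_study(study_config(seed = 19))
  kul <- pivot_to_matrix(study$ratings, "KUL", session = 1)
  expect_false(na_agreement(kul)$prevalence_flag)
  # forcing a 15% NA rate on KUL teeth must fire the audit
  cfg <- study_config(seed = 19)
  cfg$na_rate$KUL[] <- 0.15
  study2 <- generate_study(cfg)
  kul2 <- pivot_to_matrix(study2$ratings, "KUL", session = 1)
  expect_true(na_agreement(kul2)$prevalence_flag)
})
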