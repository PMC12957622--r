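test_that("CSV round-trip is lossless and NA markers are normalized", {
  tab <- toy_rating_table()
  f <- withr::local_tempfile(fileext = ".csv")
  write_ratings(tab, f)
  back <- read_ratings(f)
  expect_equal(as.data.frame(back), as.data.frame(tab))

  # dialect tolerance: NA, n/a and empty all mean missing
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,observer_id,session,tooth,method,value",
               "S1,1,1,38,DEM,D",
               "S2,1,1,38,DEM,E",
               "S3,1,1,38,DEM,n/a",
               "S4,1,1,38,DEM,NA",
               "S5,1,1,38,DEM,"), f2)
  tab2 <- read_ratings(f2)
  expect_equal(nrow(tab2), 5L)
  expect_equal(sum(is.na(tab2$value)), 3L)
})

test_that("validation rejects bad stages, duplicates and missing columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,observer_id,session,tooth,method,value",
               "S1,1,1,38,DEM,D",
               "S2,1,1,38,DEM,K"), f)
  expect_error(read_ratings(f), "rows: 2")

  df <- data.frame(subject_id = "S1", observer_id = 1L, session = 1L,
                   tooth = 38L, method = "DEM", value = "D")
  expect_error(as_rating_table(rbind(df, df)), "duplicate")
  expect_error(as_rating_table(df[, -6]), "missing required columns")
  # KUL has no maxillary teeth
  df$method <- "KUL"
  df$value <- "3"
  df$tooth <- 18L
  expect_error(as_rating_table(df), "not applicable")
  # continuous values must be non-negative numbers
  df2 <- data.frame(subject_id = "S1", observer_id = 1L, session = 1L,
                    tooth = 38L, method = "I3M", value = "-0.2")
  expect_error(as_rating_table(df2), "invalid I3M")
})

test_that("chronological age follows the 365.25 days/year convention", {
  expect_equal(chronological_age("2000-01-01", "2014-01-01"), 14,
               tolerance = 0.01)
  expect_equal(chronological_age("2000-01-01", "2000-07-01"), 0.5,
               tolerance = 0.01)
  days <- as.numeric(as.Date("2023-11-02") - as.Date("2001-03-15"))
  expect_identical(chronological_age("2001-03-15", "2023-11-02"),
                   days / 365.25)
  expect_error(chronological_age("2010-01-01", "2009-01-01"), "after")
})

test_that("pivoting stacks (subject, tooth) units and preserves NA cells", {
  study <- generate_study(study_config(seed = 3))
  tab <- study$ratings
  dem <- pivot_to_matrix(tab, "DEM", session = 1)
  expect_equal(dim(dem$values), c(200L, 9L))   # 50 subjects x 4 teeth
  kul <- pivot_to_matrix(tab, "KUL", session = 1)
  expect_equal(nrow(kul$values), 100L)         # mandibular only
  # NA conservation against the raw table slice
  slice <- tab[tab$method == "DEM" & tab$session == 1L, ]
  expect_equal(sum(is.na(dem$values)), sum(is.na(slice$value)))
  # pooled non-NA cells equal the sum over per-tooth matrices
  per_tooth <- vapply(c(18L, 28L, 38L, 48L), function(t) {
    sum(!is.na(pivot_to_matrix(tab, "DEM", session = 1,
                               teeth = t)$values))
  }, numeric(1))
  expect_equal(sum(!is.na(dem$values)), sum(per_tooth))
  expect_error(pivot_to_matrix(tab, "KUL", teeth = 18L),
               "not applicable")
})

test_that("pivoting is invariant to record order", {
  tab <- toy_rating_table()
  m1 <- pivot_to_matrix(tab, "DEM", session = 1)
  shuffled <- as_rating_table(
    as.data.frame(tab)[sample(nrow(tab)), ])
  m2 <- pivot_to_matrix(shuffled, "DEM", session = 1)
  expect_identical(m1$values, m2$values)
})

test_that("session pairs align subjects and flag NA pairs", {
  tab <- toy_rating_table()
  pr <- session_pairs(tab, 1L, "DEM", 38L)
  expect_equal(nrow(pr), 5L)
  expect_equal(pr$complete, !is.na(pr$session1) & !is.na(pr$session2))
  # order invariance
  shuffled <- as_rating_table(as.data.frame(tab)[rev(seq_len(nrow(tab))), ])
  expect_equal(session_pairs(shuffled, 1L, "DEM", 38L), pr)
  # an observer missing one session is an incomplete design
  only_s1 <- as_rating_table(as.data.frame(tab)[tab$session == 1L, ])
  expect_error(session_pairs(only_s1, 1L, "DEM", 38L), "session")
})
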