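#' Marginal stage-probability specifications for the rating simulator
#'
#' `"uniform"` gives equal mass; `"skew_low"` concentrates mass on the
#' lower stages via a truncated geometric profile (prob proportional to
#' `ratio^(q-1)`), `"skew_high"` is its mirror image.
#'
#' @param marginal `"uniform"`, `"skew_low"`, `"skew_high"`, or a numeric
#'   probability vector of length `n_categories`.
#' @param n_categories Number of ordered categories.
#' @param ratio Geometric decay used by the skewed profiles (default
#'   0.7).
#' @return Probability vector summing to 1.
#' @export
marginal_probs <- function(marginal, n_categories, ratio = 0.7) {
  if (is.numeric(marginal)) {
    if (length(marginal) != n_categories || any(marginal < 0) ||
        abs(sum(marginal) - 1) > 1e-8) {
      stop("marginal probabilities must be length n_categories, ",
           "non-negative, and sum to 1", call. = FALSE)
    }
    return(marginal / sum(marginal))
  }
  p <- switch(match.arg(marginal, c("uniform", "skew_low", "skew_high")),
    uniform = rep(1, n_categories),
    skew_low = ratio^(seq_len(n_categories) - 1),
    skew_high = rev(ratio^(seq_len(n_categories) - 1))
  )
  p / sum(p)
}

#' Simulation design for correlated ordinal ratings
#'
#' The generating mechanism: each unit draws a latent stage L from the
#' marginal distribution; each rater independently reports L with
#' probability `rho` and otherwise reports an independent draw from the
#' same marginal. Every rater's marginal distribution is therefore
#' exactly the configured one for any `rho`, raters are exchangeable, and
#' under uniform marginals with identity weights the large-sample
#' expected AC1 is exactly `rho^2`.
#'
#' @param n_units Number of subjects (units).
#' @param n_raters Number of raters (the study used 9).
#' @param n_categories Number of ordered categories (7, 8 or 10 for the
#'   staging methods studied).
#' @param marginal Marginal spec (see [marginal_probs()]).
#' @param rho Copy probability in \[0, 1\].
#' @param seed Optional integer seed.
#' @return Object of class `sim_design`.
#' @export
sim_design <- function(n_units, n_raters = 9L, n_categories = 8L,
                       marginal = "uniform", rho = 0.8, seed = NULL) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  probs <- marginal_probs(marginal, n_categories)
  structure(
    list(n_units = as.integer(n_units), n_raters = as.integer(n_raters),
         n_categories = as.integer(n_categories),
         marginal = if (is.character(marginal)) marginal else "custom",
         probs = probs, rho = rho, seed = seed),
    class = "sim_design"
  )
}

# Fast path: simulate a units x categories count matrix under the
# latent-copy mechanism, using the current RNG state.
simulate_rating_counts <- function(n_units, n_raters, probs, rho) {
  q <- length(probs)
  latent <- sample.int(q, n_units, replace = TRUE, prob = probs)
  vals <- matrix(sample.int(q, n_units * n_raters, replace = TRUE,
                            prob = probs), n_units, n_raters)
  copy <- matrix(stats::runif(n_units * n_raters) < rho, n_units,
                 n_raters)
  vals[copy] <- latent[row(vals)[copy]]
  counts <- matrix(0L, n_units, q)
  for (j in seq_len(n_raters)) {
    idx <- cbind(seq_len(n_units), vals[, j])
    counts[idx] <- counts[idx] + 1L
  }
  attr(counts, "values") <- vals
  counts
}

#' Simulate a correlated ordinal rating matrix
#'
#' @param design A [sim_design()].
#' @return A `rating_matrix` with stage labels `"1" .. "Q"`.
#' @examples
#' m <- simulate_ratings(sim_design(20, 9, 8, "uniform", rho = 1,
#'                                  seed = 1))
#' gwet_ac(m)$coefficient  # 1: all raters copy the latent stage
#' @export
simulate_ratings <- function(design) {
  if (!is.null(design$seed)) set.seed(design$seed)
  counts <- simulate_rating_counts(design$n_units, design$n_raters,
                                   design$probs, design$rho)
  vals <- attr(counts, "values")
  values <- matrix(as.character(vals), nrow(vals), ncol(vals))
  sc <- staging_scheme("SIM", as.character(seq_len(design$n_categories)),
                       c(18L, 28L, 38L, 48L))
  rating_matrix_from_values(values, sc)
}

# Weight-matrix cache over reduced alphabets: weights depend only on the
# number of observed categories for the built-in kinds.
weight_cache <- function(q_max, kind) {
  lapply(seq_len(q_max), function(q) {
    if (q == 1L) return(NULL)
    build_weights(as.character(seq_len(q)), kind)
  })
}

# AC estimate on a simulated count matrix with the per-table
# category-exclusion rule applied (never-observed categories dropped,
# weights rebuilt on the reduced alphabet).
ac_from_sim_counts <- function(counts, wcache) {
  obs <- which(colSums(counts) > 0L)
  if (length(obs) < 2L) {
    return(list(coefficient = NA_real_, se = NA_real_,
                degenerate = TRUE))
  }
  agreement_from_counts(counts[, obs, drop = FALSE],
                        wcache[[length(obs)]], "gwet")
}

sim_mean_coefficient <- function(design, rho, wcache, estimator, reps) {
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    counts <- simulate_rating_counts(design$n_units, design$n_raters,
                                     design$probs, rho)
    fit <- if (estimator == "kappa") {
      obs <- which(colSums(counts) > 0L)
      if (length(obs) < 2L) list(coefficient = NA_real_) else
        agreement_from_counts(counts[, obs, drop = FALSE],
                              diag(length(obs)), "fleiss")
    } else {
      ac_from_sim_counts(counts, wcache)
    }
    vals[r] <- fit$coefficient
  }
  mean(vals, na.rm = TRUE)
}

#' Calibrate the rating-correlation parameter to a target coefficient
#'
#' Bisection on `rho`: the Monte Carlo mean coefficient of the simulator
#' is monotone increasing in `rho` (under uniform marginals with identity
#' weights the limit is exactly `rho^2`). Each bisection step reuses the
#' same seed (common random numbers), so the result is deterministic
#' given `seed`.
#'
#' @param target Target mean coefficient in (0, 1).
#' @param design A [sim_design()]; its `rho` is ignored.
#' @param weights_kind Weight kind for the AC estimator (default
#'   `"ordinal"`, i.e. AC2; `"identity"` gives AC1).
#' @param estimator `"ac"` (Gwet, with `weights_kind`) or `"kappa"`
#'   (Fleiss-type chance term).
#' @param reps Monte Carlo replicates per bisection step.
#' @param tol Acceptable |mean - target| (default 0.004).
#' @param seed Integer seed for the common random numbers.
#' @return Calibrated `rho`.
#' @export
calibrate_rho <- function(target, design, weights_kind = "ordinal",
                          estimator = c("ac", "kappa"), reps = 400L,
                          tol = 0.004, seed = 1L) {
  estimator <- match.arg(estimator)
  if (target <= 0 || target >= 1) {
    stop("target must be in (0, 1)", call. = FALSE)
  }
  wcache <- weight_cache(design$n_categories, weights_kind)
  f <- function(rho) {
    set.seed(seed)
    sim_mean_coefficient(design, rho, wcache, estimator, reps)
  }
  f0 <- f(0)
  if (target <= f0 + tol) {
    stop(sprintf(
      "target %.3f is at or below the chance level of this design (%.3f)",
      target, f0), call. = FALSE)
  }
  lo <- 0
  hi <- 1
  mid <- NA_real_
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm - target) <= tol || (hi - lo) < 5e-4) break
    if (fm < target) lo <- mid else hi <- mid
  }
  mid
}

#' Monte Carlo power of the one-sided AC2 test
#'
#' Proportion of simulated rating matrices for which the one-sided
#' normal test of AC2 > `null_value` at level `alpha` rejects, using the
#' linearized standard error. Replicates with an undefined coefficient
#' (fewer than two observed categories) are skipped and counted; a
#' warning is emitted if more than 1% are skipped.
#'
#' @param design A [sim_design()] with calibrated `rho`.
#' @param weights_kind Weight kind for AC2 (default `"ordinal"`).
#' @param null_value Null coefficient (the study used 0.4).
#' @param alpha One-sided level (default 0.05).
#' @param reps Number of replicates.
#' @param seed Integer seed.
#' @return List of class `power_estimate`: `power`, `mc_se` (binomial
#'   Monte Carlo error), `reps_used`, `n_skipped`.
#' @export
estimate_power <- function(design, weights_kind = "ordinal",
                           null_value = 0.4, alpha = 0.05, reps = 1000L,
                           seed = 1L) {
  set.seed(seed)
  wcache <- weight_cache(design$n_categories, weights_kind)
  zcrit <- stats::qnorm(1 - alpha)
  reject <- 0L
  skipped <- 0L
  for (r in seq_len(reps)) {
    counts <- simulate_rating_counts(design$n_units, design$n_raters,
                                     design$probs, design$rho)
    fit <- ac_from_sim_counts(counts, wcache)
    if (fit$degenerate || !is.finite(fit$coefficient) ||
        is.na(fit$se)) {
      skipped <- skipped + 1L
      next
    }
    rej <- if (fit$se > 0) {
      (fit$coefficient - null_value) / fit$se > zcrit
    } else {
      fit$coefficient > null_value
    }
    if (rej) reject <- reject + 1L
  }
  used <- reps - skipped
  if (skipped > 0.01 * reps) {
    warning(sprintf("%d of %d replicates skipped as degenerate",
                    skipped, reps))
  }
  power <- if (used > 0) reject / used else NA_real_
  structure(
    list(power = power,
         mc_se = if (used > 0) sqrt(power * (1 - power) / used) else
           NA_real_,
         reps_used = used, n_skipped = skipped),
    class = "power_estimate"
  )
}

#' Minimum sample size for target power of the AC2 test
#'
#' For each (marginal distribution, category count) condition: calibrate
#' `rho` so the simulated mean AC2 equals `target_ac2`, then walk the
#' ascending `n_grid` estimating power of the one-sided test against
#' `null_ac2` until `target_power` is reached. The per-condition minimum
#' n and the overall recommended n (max over conditions) are extracted.
#'
#' @param n_raters Number of raters (default 9).
#' @param categories Category counts to cover (default `c(7, 8, 10)`,
#'   the stage counts of the three staging methods).
#' @param marginals Marginal specs (default uniform plus both skews).
#' @param n_grid Ascending candidate sample sizes.
#' @param target_power Required power (default 0.8).
#' @param target_ac2 True mean AC2 the simulator is calibrated to
#'   (default 0.6).
#' @param null_ac2 Null AC2 of the test (default 0.4).
#' @param alpha One-sided level (default 0.05).
#' @param weights_kind Weight kind for AC2 (default `"ordinal"`).
#' @param reps Power replicates per grid point (default 1000).
#' @param calib_reps Replicates per calibration step (default 400).
#' @param calib_n Unit count used during calibration (default 50, the
#'   study sample size).
#' @param seed Integer seed; all sub-seeds derive from it.
#' @param early_stop Stop walking the grid for a condition once target
#'   power is reached (remaining grid points left NA).
#' @return Object of class `power_grid`: `grid` (one row per evaluated
#'   (condition, n)), `min_n` (per condition), `recommended_n`, and the
#'   settings.
#' @export
min_n_for_power <- function(n_raters = 9L, categories = c(7L, 8L, 10L),
                            marginals = c("uniform", "skew_low",
                                          "skew_high"),
                            n_grid = c(5L, 10L, 15L, 20L, 25L, 30L, 40L,
                                       50L),
                            target_power = 0.8, target_ac2 = 0.6,
                            null_ac2 = 0.4, alpha = 0.05,
                            weights_kind = "ordinal", reps = 1000L,
                            calib_reps = 400L, calib_n = 50L, seed = 42L,
                            early_stop = TRUE) {
  if (is.unsorted(n_grid)) stop("n_grid must be ascending", call. = FALSE)
  conditions <- expand.grid(marginal = marginals,
                            n_categories = categories,
                            KEEP.OUT.ATTRS = FALSE,
                            stringsAsFactors = FALSE)
  set.seed(seed)
  n_seeds <- nrow(conditions) * (1L + length(n_grid))
  subseeds <- sample.int(.Machine$integer.max - 1L, n_seeds)
  grid <- list()
  min_n <- rep(NA_integer_, nrow(conditions))
  rho_cal <- rep(NA_real_, nrow(conditions))
  s <- 0L
  for (ci in seq_len(nrow(conditions))) {
    marg <- conditions$marginal[ci]
    q <- conditions$n_categories[ci]
    s <- s + 1L
    des_cal <- sim_design(calib_n, n_raters, q, marg)
    rho <- calibrate_rho(target_ac2, des_cal, weights_kind,
                         reps = calib_reps, seed = subseeds[s])
    rho_cal[ci] <- rho
    done <- FALSE
    for (gi in seq_along(n_grid)) {
      s_n <- subseeds[s + gi]
      if (done) next
      n <- n_grid[gi]
      des <- sim_design(n, n_raters, q, marg, rho = rho)
      pw <- estimate_power(des, weights_kind, null_ac2, alpha, reps,
                           seed = s_n)
      grid[[length(grid) + 1L]] <- data.frame(
        marginal = marg, n_categories = q, rho = rho, n = n,
        power = pw$power, mc_se = pw$mc_se, reps_used = pw$reps_used,
        stringsAsFactors = FALSE)
      if (!is.na(pw$power) && pw$power >= target_power) {
        min_n[ci] <- n
        if (early_stop) done <- TRUE
      } else if (is.na(min_n[ci])) {
        min_n[ci] <- NA_integer_
      }
    }
    # smallest grid n with power >= target (first hit wins under
    # early_stop; otherwise recompute from the full grid)
    if (!early_stop) {
      sub <- do.call(rbind, grid)
      sub <- sub[sub$marginal == marg & sub$n_categories == q, ]
      hit <- sub$n[!is.na(sub$power) & sub$power >= target_power]
      min_n[ci] <- if (length(hit) > 0) min(hit) else NA_integer_
    }
    s <- s + length(n_grid)
  }
  out_min <- cbind(conditions, rho = rho_cal, min_n = min_n)
  structure(
    list(grid = do.call(rbind, grid), min_n = out_min,
         recommended_n = if (all(!is.na(min_n))) max(min_n) else
           NA_integer_,
         settings = list(n_raters = n_raters, target_power = target_power,
                         target_ac2 = target_ac2, null_ac2 = null_ac2,
                         alpha = alpha, weights_kind = weights_kind,
                         reps = reps, calib_reps = calib_reps,
                         calib_n = calib_n, n_grid = n_grid,
                         seed = seed)),
    class = "power_grid"
  )
}

#' @export
print.power_grid <- function(x, ...) {
  cat(sprintf(
    "<power_grid> %d conditions, target AC2 %.2f vs null %.2f, power >= %.0f%%\n",
    nrow(x$min_n), x$settings$target_ac2, x$settings$null_ac2,
    100 * x$settings$target_power))
  print(x$min_n, row.names = FALSE)
  cat(sprintf("recommended n (max over conditions): %s\n",
              x$recommended_n))
  invisible(x)
}

#' Bonett's sample size for ICC confidence-interval precision
#'
#' Closed-form approximation for the number of subjects needed so that
#' the 95% (or other) confidence interval for an ICC with planning value
#' `rho_plan` and `k_raters` raters has total width `2 * halfwidth`:
#' \deqn{n = \lceil 8 z^2 (1-\rho)^2 (1+(k-1)\rho)^2 / (k (k-1) w^2) +
#'   1 \rceil}
#' with w the full interval width and z the standard-normal quantile.
#'
#' @param rho_plan Planning ICC in (0, 1).
#' @param k_raters Number of raters (>= 2).
#' @param halfwidth Desired CI half-width (> 0).
#' @param confidence Confidence level (default 0.95).
#' @return Required number of subjects (integer).
#' @examples
#' bonett_icc_n(0.8, 9, 0.1)  # 25
#' @export
bonett_icc_n <- function(rho_plan, k_raters, halfwidth,
                         confidence = 0.95) {
  if (rho_plan <= 0 || rho_plan >= 1) {
    stop("rho_plan must be in (0, 1)", call. = FALSE)
  }
  if (k_raters < 2) stop("k_raters must be >= 2", call. = FALSE)
  if (halfwidth <= 0) stop("halfwidth must be > 0", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) {
    stop("confidence must be in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  w <- 2 * halfwidth
  k <- k_raters
  as.integer(ceiling(
    8 * z^2 * (1 - rho_plan)^2 * (1 + (k - 1) * rho_plan)^2 /
      (k * (k - 1) * w^2) + 1
  ))
}

#' Simulation-based precision sample size for agreement coefficients
#'
#' Generic CI-precision search: calibrate the simulator to the expected
#' coefficient, then find the smallest grid n whose Monte Carlo median
#' 95% CI half-width is at most `halfwidth`. This is the simulation
#' analogue of closed-form precision formulas for multi-rater kappa,
#' usable for kappa, AC1 and AC2 alike.
#'
#' @param coefficient `"kappa"` (Fleiss-type), `"ac1"` or `"ac2"`.
#' @param expected Expected coefficient in (0, 1).
#' @param halfwidth Target median CI half-width.
#' @param n_raters,n_categories,marginal Simulator design.
#' @param weights_kind Weight kind when `coefficient = "ac2"`.
#' @param n_grid Ascending candidate sample sizes.
#' @param reps Replicates per grid point.
#' @param seed Integer seed.
#' @return Object of class `precision_n`: `n` (smallest adequate grid n,
#'   NA if unattained), `rho`, and `grid` (n, median half-width, MC
#'   spread).
#' @export
precision_n_simulated <- function(coefficient = c("kappa", "ac1", "ac2"),
                                  expected, halfwidth, n_raters = 9L,
                                  n_categories = 5L,
                                  marginal = "uniform",
                                  weights_kind = "ordinal",
                                  n_grid = c(10L, 20L, 30L, 50L, 75L,
                                             100L, 150L, 200L),
                                  reps = 300L, seed = 1L) {
  coefficient <- match.arg(coefficient)
  if (expected <= 0 || expected >= 1) {
    stop("expected must be in (0, 1)", call. = FALSE)
  }
  if (is.unsorted(n_grid)) stop("n_grid must be ascending", call. = FALSE)
  kind <- switch(coefficient, kappa = "identity", ac1 = "identity",
                 ac2 = weights_kind)
  estimator <- if (coefficient == "kappa") "kappa" else "ac"
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L,
                         1L + length(n_grid))
  des_cal <- sim_design(max(50L, min(n_grid)), n_raters, n_categories,
                        marginal)
  rho <- calibrate_rho(expected, des_cal, kind, estimator,
                       reps = 400L, seed = subseeds[1])
  wcache <- weight_cache(n_categories, kind)
  rows <- list()
  n_found <- NA_integer_
  for (gi in seq_along(n_grid)) {
    n <- n_grid[gi]
    set.seed(subseeds[1L + gi])
    hw <- numeric(reps)
    for (r in seq_len(reps)) {
      counts <- simulate_rating_counts(n, n_raters,
                                       marginal_probs(marginal,
                                                      n_categories),
                                       rho)
      fit <- if (estimator == "kappa") {
        obs <- which(colSums(counts) > 0L)
        if (length(obs) < 2L) list(se = NA_real_) else
          agreement_from_counts(counts[, obs, drop = FALSE],
                                diag(length(obs)), "fleiss")
      } else {
        ac_from_sim_counts(counts, wcache)
      }
      hw[r] <- if (is.null(fit$se) || is.na(fit$se)) NA_real_ else
        stats::qnorm(0.975) * fit$se
    }
    med <- stats::median(hw, na.rm = TRUE)
    rows[[gi]] <- data.frame(n = n, median_halfwidth = med,
                             iqr_halfwidth = stats::IQR(hw, na.rm = TRUE))
    if (is.na(n_found) && is.finite(med) && med <= halfwidth) {
      n_found <- n
      break
    }
  }
  structure(
    list(n = n_found, rho = rho, coefficient = coefficient,
         expected = expected, halfwidth = halfwidth,
         grid = do.call(rbind, rows)),
    class = "precision_n"
  )
}

#' @export
print.precision_n <- function(x, ...) {
  cat(sprintf(
    "<precision_n> %s, expected %.2f, target half-width %.3f -> n = %s (rho %.3f)\n",
    x$coefficient, x$expected, x$halfwidth, x$n, x$rho))
  invisible(x)
}
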