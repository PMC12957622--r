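# Stage marginal probabilities and NA rates emulating the published
# categorical distributions of the 50-subject, 9-observer study (counts
# per tooth out of 450 session-1 cells; stage probabilities are over
# assessable cells, NA imposed independently).
study_stage_counts <- function() {
  list(
    KUL = list(
      `38` = c(`1` = 77, `2` = 75, `3` = 58, `4` = 112, `5` = 78,
               `6` = 35, `7` = 14),
      `48` = c(`1` = 74, `2` = 66, `3` = 66, `4` = 102, `5` = 81,
               `6` = 34, `7` = 24)
    ),
    DEM = list(
      `18` = c(A = 0, B = 0, C = 0, D = 46, E = 122, F = 135, G = 85,
               H = 41),
      `28` = c(A = 0, B = 0, C = 0, D = 48, E = 124, F = 136, G = 82,
               H = 39),
      `38` = c(A = 0, B = 0, C = 4, D = 74, E = 115, F = 166, G = 70,
               H = 21),
      `48` = c(A = 0, B = 0, C = 3, D = 68, E = 116, F = 147, G = 82,
               H = 30)
    ),
    GHK = list(
      `18` = c(`1` = 0, `2` = 0, `3` = 5, `4` = 54, `5` = 88, `6` = 97,
               `7` = 69, `8` = 46, `9` = 35, `10` = 34),
      `28` = c(`1` = 0, `2` = 0, `3` = 5, `4` = 57, `5` = 85, `6` = 100,
               `7` = 67, `8` = 49, `9` = 31, `10` = 36),
      `38` = c(`1` = 0, `2` = 1, `3` = 12, `4` = 64, `5` = 101, `6` = 82,
               `7` = 91, `8` = 59, `9` = 23, `10` = 16),
      `48` = c(`1` = 0, `2` = 1, `3` = 8, `4` = 64, `5` = 99, `6` = 86,
               `7` = 76, `8` = 61, `9` = 24, `10` = 27)
    )
  )
}

study_na_counts <- function() {
  list(
    KUL = c(`38` = 1, `48` = 3),
    DEM = c(`18` = 21, `28` = 21, `38` = 0, `48` = 4),
    GHK = c(`18` = 22, `28` = 20, `38` = 1, `48` = 4),
    I3M = c(`38` = 1, `48` = 7)
  )
}

#' Configuration for the synthetic multi-observer study
#'
#' Defaults emulate the real study design: 50 subjects aged 14-23.99
#' years (19 male, 31 female), 9 observers, 2 sessions two weeks apart,
#' four third molars, four methods. Stage marginals and NA rates default
#' to the published per-tooth distributions (450 session-1 cells per
#' tooth); the I3M truth is log-normal matched to the published medians
#' (0.27 / 0.26) and quartile spreads.
#'
#' Ordinal ratings use the latent-copy mechanism of [sim_design()] with
#' per-method correlation `inter_rho`; session 2 repeats the session-1
#' value with probability `intra_repeat_agreement` and is otherwise
#' regenerated from the same latent stage. I3M readings multiply the
#' subject truth by log-normal observer noise (`i3m_noise_sdlog`), so
#' exact repeats are essentially impossible, as for any metric method.
#' NA responses are imposed independently of the stage.
#'
#' @param n_subjects,n_observers Study dimensions (defaults 50 and 9).
#' @param inter_rho Named or scalar copy probability for the ordinal
#'   methods (default 0.9, putting simulated inter-observer AC2 in the
#'   high-agreement band reported for trained observers).
#' @param intra_repeat_agreement Probability a session-2 ordinal rating
#'   repeats session 1 exactly (default 0.95).
#' @param i3m_noise_sdlog Log-scale observer/session noise sd for I3M
#'   (default 0.05, i.e. about 5% multiplicative error).
#' @param stage_marginals,na_rate Optional overrides, in the structure of
#'   the defaults (per method, per tooth).
#' @param age_range,sex_counts Subject metadata generation.
#' @param seed Integer seed.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_subjects = 50L, n_observers = 9L,
                         inter_rho = 0.9,
                         intra_repeat_agreement = 0.95,
                         i3m_noise_sdlog = 0.05,
                         stage_marginals = NULL, na_rate = NULL,
                         age_range = c(14, 23.99),
                         sex_counts = c(male = 19L, female = 31L),
                         seed = 1L) {
  schemes <- default_schemes()
  counts <- study_stage_counts()
  nas <- study_na_counts()
  if (is.null(stage_marginals)) {
    stage_marginals <- lapply(counts, function(m) {
      lapply(m, function(v) v / sum(v))
    })
  }
  if (is.null(na_rate)) {
    na_rate <- lapply(nas, function(v) v / 450)
  }
  for (m in names(stage_marginals)) {
    for (t in names(stage_marginals[[m]])) {
      p <- stage_marginals[[m]][[t]]
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        stop(sprintf("stage marginals for %s tooth %s must sum to 1",
                     m, t), call. = FALSE)
      }
    }
  }
  rho <- inter_rho
  if (length(rho) == 1L && is.null(names(rho))) {
    rho <- c(KUL = rho, DEM = rho, GHK = rho)
  }
  # Log-normal I3M truth: meanlog from the published median, sdlog from
  # the quartile ratio Q3/Q1 = exp(2 * 0.6745 * sdlog).
  zq <- stats::qnorm(0.75)
  i3m_params <- list(
    `38` = list(meanlog = log(0.27), sdlog = log(0.45 / 0.18) / (2 * zq)),
    `48` = list(meanlog = log(0.26), sdlog = log(0.42 / 0.17) / (2 * zq))
  )
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_observers = as.integer(n_observers), sessions = 2L,
         schemes = schemes, stage_marginals = stage_marginals,
         na_rate = na_rate, inter_rho = rho,
         intra_repeat_agreement = intra_repeat_agreement,
         i3m_params = i3m_params, i3m_noise_sdlog = i3m_noise_sdlog,
         age_range = age_range, sex_counts = sex_counts,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

draw_stage <- function(latent, probs, rho, n) {
  cats <- names(probs)
  copy <- stats::runif(n) < rho
  out <- latent
  k <- sum(!copy)
  if (k > 0) {
    out[!copy] <- sample(cats, k, replace = TRUE, prob = probs)
  }
  out
}

#' Generate a complete synthetic multi-observer staging study
#'
#' Draws a full two-session rating table plus subject metadata under the
#' mechanism documented in [study_config()], and a truth record holding
#' every generating parameter (latent stages, I3M truths, config) so the
#' pipeline's estimates can be compared to known values.
#'
#' @param config A [study_config()].
#' @return List with `ratings` (a `rating_table`), `subjects` (metadata
#'   data frame with chronological age), and `truth`.
#' @examples
#' study <- generate_study(study_config(seed = 7))
#' nrow(study$ratings)  # 10800 = (2+4+4+2 teeth) x 50 x 9 x 2
#' @export
generate_study <- function(config) {
  set.seed(config$seed)
  ns <- config$n_subjects
  no <- config$n_observers
  subject_id <- sprintf("S%03d", seq_len(ns))
  sex <- sample(rep(names(config$sex_counts), config$sex_counts))[
    seq_len(ns)]
  age <- stats::runif(ns, config$age_range[1], config$age_range[2])
  exposure <- as.Date("2024-06-15") + sample.int(180L, ns,
                                                 replace = TRUE)
  dob <- exposure - round(age * 365.25)
  subjects <- data.frame(
    subject_id = subject_id, sex = sex, dob = dob,
    exposure_date = exposure,
    chronological_age = chronological_age(dob, exposure),
    stringsAsFactors = FALSE
  )
  rows <- list()
  truth <- list(config = config, latent = list(), i3m_truth = list())
  for (m in names(config$stage_marginals)) {
    sc <- config$schemes[[m]]
    rho <- config$inter_rho[[m]]
    for (t in names(config$stage_marginals[[m]])) {
      probs <- config$stage_marginals[[m]][[t]]
      na_p <- config$na_rate[[m]][[t]]
      latent <- sample(names(probs), ns, replace = TRUE, prob = probs)
      truth$latent[[m]][[t]] <- latent
      for (obs in seq_len(no)) {
        s1 <- draw_stage(latent, probs, rho, ns)
        s1[stats::runif(ns) < na_p] <- NA_character_
        repeat_s1 <- stats::runif(ns) < config$intra_repeat_agreement
        s2 <- draw_stage(latent, probs, rho, ns)
        s2[stats::runif(ns) < na_p] <- NA_character_
        s2[repeat_s1] <- s1[repeat_s1]
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = rep(subject_id, 2L),
          observer_id = obs,
          session = rep(c(1L, 2L), each = ns),
          tooth = as.integer(t), method = m,
          value = c(s1, s2), stringsAsFactors = FALSE)
      }
    }
  }
  for (t in names(config$i3m_params)) {
    par <- config$i3m_params[[t]]
    na_p <- config$na_rate$I3M[[t]]
    tv <- stats::rlnorm(ns, par$meanlog, par$sdlog)
    truth$i3m_truth[[t]] <- tv
    for (obs in seq_len(no)) {
      s1 <- tv * exp(stats::rnorm(ns, 0, config$i3m_noise_sdlog))
      s2 <- tv * exp(stats::rnorm(ns, 0, config$i3m_noise_sdlog))
      s1 <- sprintf("%.2f", s1)
      s2 <- sprintf("%.2f", s2)
      s1[stats::runif(ns) < na_p] <- NA_character_
      s2[stats::runif(ns) < na_p] <- NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = rep(subject_id, 2L),
        observer_id = obs,
        session = rep(c(1L, 2L), each = ns),
        tooth = as.integer(t), method = "I3M",
        value = c(s1, s2), stringsAsFactors = FALSE)
    }
  }
  ratings <- do.call(rbind, rows)
  ratings <- as_rating_table(ratings, config$schemes)
  list(ratings = ratings, subjects = subjects, truth = truth)
}

#' Compare pipeline estimates against the generating parameters
#'
#' Runs the agreement pipeline on a generated study and reports each
#' estimate next to the value implied by the generator: intra-observer
#' kappa against the session-repeat probability, inter-observer I3M ICC
#' against the closed-form variance-ratio truth of the log-normal noise
#' model, and inter-observer AC2 per ordinal method (whose analytic
#' reference rho^2 is exact only under uniform marginals with identity
#' weights, so it is reported as context, not a target).
#'
#' @param study Output of [generate_study()].
#' @param weights_kind Weight kind for inter-observer AC2.
#' @return Data frame with `quantity`, `estimate`, `reference`, `note`.
#' @export
recover_parameters <- function(study, weights_kind = "ordinal") {
  config <- study$truth$config
  tab <- study$ratings
  out <- list()
  for (m in c("KUL", "DEM", "GHK")) {
    mat <- pivot_to_matrix(tab, m, session = 1L, pooling = "overall")
    w <- build_weights(observed_categories(mat), weights_kind)
    ac <- gwet_ac(mat, w)
    out[[length(out) + 1L]] <- data.frame(
      quantity = sprintf("inter AC2 (%s)", m),
      estimate = ac$coefficient,
      reference = config$inter_rho[[m]]^2,
      note = "rho^2 is exact only for uniform marginals + identity weights",
      stringsAsFactors = FALSE)
    kap <- vapply(seq_len(config$n_observers), function(obs) {
      teeth <- config$schemes[[m]]$applicable_teeth
      mean(vapply(teeth, function(t) {
        pr <- session_pairs(tab, obs, m, t)
        k <- cohen_kappa_weighted(pr[pr$complete, ],
                                  scheme_categories =
                                    config$schemes[[m]]$categories,
                                  kind = weights_kind)
        if (k$degenerate) NA_real_ else k$coefficient
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      quantity = sprintf("mean intra kappa (%s)", m),
      estimate = mean(kap),
      reference = config$intra_repeat_agreement,
      note = "kappa >= repeat prob net of chance corrections",
      stringsAsFactors = FALSE)
  }
  for (t in c(38L, 48L)) {
    mat <- pivot_to_matrix(tab, "I3M", session = 1L, teeth = t)
    fit <- icc_absolute(mat)
    par <- config$i3m_params[[as.character(t)]]
    s2 <- exp(par$sdlog^2) - 1
    e2 <- exp(par$sdlog^2) * (exp(config$i3m_noise_sdlog^2) - 1)
    out[[length(out) + 1L]] <- data.frame(
      quantity = sprintf("inter ICC (I3M %d)", t),
      estimate = fit$icc,
      reference = s2 / (s2 + e2),
      note = "log-normal variance-component truth",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
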