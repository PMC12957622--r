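#' Agreement result container
#'
#' @param coefficient Point estimate.
#' @param se Standard error (unit-level linearization or large-sample).
#' @param n_units Number of analysis units contributing.
#' @param n_observations Number of non-NA ratings used.
#' @param null_value Null value for the test (default 0).
#' @param sided `"two"` or `"one"` (one-sided tests the coefficient being
#'   greater than `null_value`, as in the power analysis).
#' @param method Label describing the coefficient.
#' @param pa,pe Observed and chance agreement components.
#' @param degenerate TRUE when the coefficient is undefined (e.g. a
#'   single observed category, or both raters constant); batch pipelines
#'   receive a flagged result rather than an error.
#' @return Object of class `agreement_result`.
#' @keywords internal
agreement_result <- function(coefficient, se, n_units, n_observations,
                             null_value = 0, sided = "two",
                             method = "agreement", pa = NA_real_,
                             pe = NA_real_, degenerate = FALSE) {
  if (degenerate || !is.finite(coefficient)) {
    res <- list(coefficient = NA_real_, se = NA_real_, ci_low = NA_real_,
                ci_high = NA_real_, p_value = NA_real_,
                n_units = n_units, n_observations = n_observations,
                null_value = null_value, sided = sided, method = method,
                pa = pa, pe = pe, degenerate = TRUE)
    return(structure(res, class = "agreement_result"))
  }
  z <- stats::qnorm(0.975)
  ci_low <- max(-1, coefficient - z * se)
  ci_high <- min(1, coefficient + z * se)
  zstat <- if (se > 0) (coefficient - null_value) / se else
    sign(coefficient - null_value) * Inf
  p_value <- if (sided == "one") {
    stats::pnorm(zstat, lower.tail = FALSE)
  } else {
    2 * stats::pnorm(abs(zstat), lower.tail = FALSE)
  }
  if (!is.finite(zstat)) p_value <- if (coefficient == null_value) 1 else 0
  structure(
    list(coefficient = coefficient, se = se, ci_low = ci_low,
         ci_high = ci_high, p_value = min(1, p_value), n_units = n_units,
         n_observations = n_observations, null_value = null_value,
         sided = sided, method = method, pa = pa, pe = pe,
         degenerate = FALSE),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<%s> degenerate (undefined); n_units=%d, n_obs=%d\n",
                x$method, x$n_units, x$n_observations))
    return(invisible(x))
  }
  cat(sprintf(
    "<%s> %.3f [%.3f; %.3f], se %.4f, p %s (%s-sided vs %g), n_units=%d, n_obs=%d\n",
    x$method, x$coefficient, x$ci_low, x$ci_high, x$se,
    format.pval(x$p_value, digits = 3, eps = 1e-3), x$sided, x$null_value,
    x$n_units, x$n_observations))
  cat(sprintf("  benchmark: %s (Landis-Koch)\n",
              benchmark_label(x$coefficient, "landis_koch")))
  invisible(x)
}

# units x categories count matrix over an explicit category alphabet;
# units with zero non-NA ratings are kept (callers drop them).
count_matrix <- function(values, categories) {
  n <- nrow(values)
  counts <- matrix(0L, n, length(categories),
                   dimnames = list(rownames(values), categories))
  for (j in seq_len(ncol(values))) {
    idx <- match(values[, j], categories)
    ok <- which(!is.na(idx))
    ii <- cbind(ok, idx[ok])
    counts[ii] <- counts[ii] + 1L
  }
  counts
}

# Core estimator for AC1/AC2/Fleiss-type coefficients on a count matrix.
# pa: mean (over units with >= 2 ratings) weighted pairwise agreement.
# pe: "gwet"  -> T_w/(Q(Q-1)) * sum_q pi_q (1 - pi_q)
#     "fleiss"-> sum_q pi_q^2 (identity weights assumed by callers)
# Variance: Gwet's unit-level linearization, no finite-population
# correction.
agreement_from_counts <- function(counts, W, pe_type = c("gwet", "fleiss")) {
  pe_type <- match.arg(pe_type)
  ri <- rowSums(counts)
  counts <- counts[ri >= 1L, , drop = FALSE]
  ri <- ri[ri >= 1L]
  n <- nrow(counts)
  q <- ncol(counts)
  n_obs <- sum(ri)
  n2 <- sum(ri >= 2L)
  if (n2 < 1L) {
    return(list(coefficient = NA_real_, se = NA_real_, pa = NA_real_,
                pe = NA_real_, n_units = n, n2 = n2, n_obs = n_obs,
                degenerate = TRUE))
  }
  ci <- counts / ri
  piq <- colMeans(ci)
  cw <- counts %*% W
  den <- ri * (ri - 1)
  den[den == 0] <- 1
  pa_i <- rowSums(counts * (cw - 1)) / den
  pa <- sum(pa_i[ri >= 2L]) / n2
  if (pe_type == "gwet") {
    if (q < 2L) {
      return(list(coefficient = NA_real_, se = NA_real_, pa = pa,
                  pe = NA_real_, n_units = n, n2 = n2, n_obs = n_obs,
                  degenerate = TRUE))
    }
    tw <- sum(W)
    pe <- tw / (q * (q - 1)) * sum(piq * (1 - piq))
    pe_i <- tw / (q * (q - 1)) * as.vector(ci %*% (1 - piq))
  } else {
    pe <- sum(piq^2)
    pe_i <- as.vector(ci %*% piq)
  }
  if (pe >= 1) {
    return(list(coefficient = NA_real_, se = NA_real_, pa = pa, pe = pe,
                n_units = n, n2 = n2, n_obs = n_obs, degenerate = TRUE))
  }
  coef <- (pa - pe) / (1 - pe)
  if (n < 2L) {
    se <- NA_real_
  } else {
    coef_i <- (n / n2) * (pa_i - pe * (ri >= 2L)) / (1 - pe)
    coef_i_x <- coef_i - 2 * (1 - coef) * (pe_i - pe) / (1 - pe)
    se <- sqrt(sum((coef_i_x - coef)^2) / (n * (n - 1)))
  }
  list(coefficient = coef, se = se, pa = pa, pe = pe, n_units = n,
       n2 = n2, n_obs = n_obs, degenerate = FALSE)
}

matrix_counts_for_weights <- function(matrix, weights) {
  cats <- colnames(weights)
  bad <- setdiff(unique(matrix$values[!is.na(matrix$values)]), cats)
  if (length(bad) > 0L) {
    stop("matrix contains categories absent from the weight matrix: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  count_matrix(matrix$values, cats)
}

#' Weighted percent agreement
#'
#' Average over units (with at least two non-NA ratings) of the weighted
#' pairwise agreement among that unit's raters; identity weights give the
#' plain proportion of matching rater pairs. Units are weighted equally.
#'
#' @param matrix A `rating_matrix` (ordinal).
#' @param weights Weight matrix from [build_weights()]; defaults to
#'   identity over the observed categories.
#' @return The observed agreement p_a in \[0, 1\].
#' @export
percent_agreement <- function(matrix, weights = NULL) {
  if (is.null(weights)) {
    weights <- build_weights(observed_categories(matrix), "identity")
  }
  counts <- matrix_counts_for_weights(matrix, weights)
  fit <- agreement_from_counts(counts, weights, "gwet")
  if (fit$n2 < 1L) {
    stop("no unit has two or more non-NA ratings", call. = FALSE)
  }
  fit$pa
}

#' Gwet's AC1 / AC2 agreement coefficient
#'
#' Chance-corrected agreement whose chance term is built from mean
#' category prevalences, making it robust to the kappa paradox under
#' imbalanced stage distributions. With identity weights this is AC1
#' (nominal); with ordinal-style weights it is AC2, the weighted
#' generalization preferred for ordered stages. Missing ratings are
#' dropped within units; units keep contributing through their remaining
#' raters.
#'
#' The estimator on a units-by-categories count table with `r_iq` raters
#' placing unit i in category q is
#' \deqn{p_a = \frac{1}{n'}\sum_{i: r_i \ge 2}\sum_q
#'   \frac{r_{iq}(r^\star_{iq}-1)}{r_i(r_i-1)}, \qquad
#'   p_e = \frac{T_w}{Q(Q-1)}\sum_q \pi_q(1-\pi_q),}
#' with \eqn{r^\star_{iq} = \sum_l w_{ql} r_{il}}, \eqn{\pi_q} the
#' across-unit mean classification proportion, and \eqn{T_w} the sum of
#' all weights; \eqn{AC = (p_a - p_e)/(1 - p_e)}. The standard error is
#' the unit-level linearization.
#'
#' @param matrix A `rating_matrix` (ordinal).
#' @param weights Weight matrix over the category alphabet to analyze;
#'   defaults to identity over [observed_categories()] (i.e. AC1 with the
#'   conservative category-exclusion rule applied).
#' @param null_value Null value tested against (default 0).
#' @param sided `"two"` (default) or `"one"`.
#' @return An `agreement_result`.
#' @examples
#' sc <- staging_scheme("X", c("A", "B"), c(38L, 48L))
#' m <- rating_matrix_from_values(
#'   matrix(c("A", "A", "B", "A", "A", "A", "B", "B"), 4, 2), sc)
#' gwet_ac(m)
#' @export
gwet_ac <- function(matrix, weights = NULL, null_value = 0,
                    sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (is.null(weights)) {
    weights <- build_weights(observed_categories(matrix), "identity")
  }
  counts <- matrix_counts_for_weights(matrix, weights)
  fit <- agreement_from_counts(counts, weights, "gwet")
  label <- if (attr(weights, "kind") %||% "identity" == "identity")
    "Gwet AC1" else
    sprintf("Gwet AC2 (%s weights)", attr(weights, "kind"))
  agreement_result(fit$coefficient, fit$se, fit$n_units, fit$n_obs,
                   null_value, sided, label, fit$pa, fit$pe,
                   fit$degenerate)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fleiss' kappa for multiple raters
#'
#' Missing-tolerant generalized kappa with chance agreement
#' \eqn{p_e = \sum_q \pi_q^2}. Provided to demonstrate the kappa paradox
#' (artificially low values under dominant categories despite high raw
#' agreement), not for headline reporting.
#'
#' @inheritParams gwet_ac
#' @return An `agreement_result`.
#' @export
fleiss_kappa <- function(matrix, null_value = 0, sided = c("two", "one")) {
  sided <- match.arg(sided)
  cats <- observed_categories(matrix)
  weights <- build_weights(cats, "identity")
  counts <- count_matrix(matrix$values, cats)
  fit <- agreement_from_counts(counts, weights, "fleiss")
  agreement_result(fit$coefficient, fit$se, fit$n_units, fit$n_obs,
                   null_value, sided, "Fleiss kappa", fit$pa, fit$pe,
                   fit$degenerate)
}

#' Weighted Cohen's kappa for paired ratings
#'
#' Two-rating agreement (used intra-observer: session 1 vs session 2).
#' \eqn{\kappa_w = (p_o - p_e)/(1 - p_e)} with \eqn{p_o = \sum w_{kl}
#' p_{kl}} over joint proportions and \eqn{p_e = \sum w_{kl} p_{k\cdot}
#' p_{\cdot l}} over marginal products. The standard error is the
#' Fleiss-Cohen-Everitt large-sample variance; the 95% CI is truncated to
#' \[-1, 1\]. NA pairs must be excluded beforehand (see
#' [session_pairs()]); pairs with either side NA are dropped here with the
#' dropped count reflected in `n_observations`.
#'
#' When both ratings are constant on one category the chance agreement is
#' 1 and kappa is undefined; a flagged degenerate result is returned.
#'
#' @param pairs Two-column matrix/data frame of stage labels, or the
#'   output of [session_pairs()].
#' @param weights Weight matrix from [build_weights()]; defaults to
#'   ordinal weights over the categories observed in the pairs, in the
#'   order of `scheme_categories` when supplied.
#' @param scheme_categories Optional full ordered alphabet used to order
#'   (and restrict) observed categories.
#' @param kind Weight kind used when `weights` is NULL.
#' @return An `agreement_result`.
#' @export
cohen_kappa_weighted <- function(pairs, weights = NULL,
                                 scheme_categories = NULL,
                                 kind = "ordinal") {
  if (is.data.frame(pairs) && all(c("session1", "session2") %in%
                                  names(pairs))) {
    pairs <- cbind(pairs$session1, pairs$session2)
  }
  pairs <- as.matrix(pairs)
  keep <- stats::complete.cases(pairs)
  x <- pairs[keep, 1]
  y <- pairs[keep, 2]
  n <- length(x)
  if (n < 2L) stop("need at least two complete pairs", call. = FALSE)
  if (is.null(weights)) {
    seen <- unique(c(x, y))
    cats <- if (is.null(scheme_categories)) sort(seen) else
      scheme_categories[scheme_categories %in% seen]
    if (length(cats) == 1L) kind <- "identity"
    weights <- build_weights(cats, kind)
  }
  cats <- colnames(weights)
  bad <- setdiff(unique(c(x, y)), cats)
  if (length(bad) > 0L) {
    stop("pair values absent from weight categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  q <- length(cats)
  p <- matrix(0, q, q, dimnames = list(cats, cats))
  tab <- table(factor(x, cats), factor(y, cats))
  p[] <- tab / n
  prow <- rowSums(p)
  pcol <- colSums(p)
  po <- sum(weights * p)
  pe <- sum(weights * outer(prow, pcol))
  if (pe >= 1 - 1e-12) {
    return(agreement_result(NA_real_, NA_real_, n, 2L * n,
                            method = "Cohen kappa (weighted)",
                            pa = po, pe = pe, degenerate = TRUE))
  }
  kap <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt (1969) large-sample variance of weighted kappa
  wbar_row <- as.vector(weights %*% pcol)   # wbar_i. = sum_j p.j w_ij
  wbar_col <- as.vector(prow %*% weights)   # wbar_.j = sum_i pi. w_ij
  term <- weights * (1 - pe) -
    outer(wbar_row, rep(1, q)) * (1 - po) -
    outer(rep(1, q), wbar_col) * (1 - po)
  # term_ij = w_ij (1-pe) - (wbar_i. + wbar_.j)(1-po)
  var_k <- (sum(p * term^2) - (po * pe - 2 * pe + po)^2) /
    (n * (1 - pe)^4)
  se <- sqrt(max(0, var_k))
  agreement_result(kap, se, n, 2L * n, method = "Cohen kappa (weighted)",
                   pa = po, pe = pe)
}

#' Verbal benchmark for a reliability coefficient
#'
#' Landis-Koch bins (kappa-type coefficients): below 0 poor, 0-0.20
#' slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80 substantial,
#' 0.81-1.0 almost perfect. Portney-Watkins bins (ICC): below 0.5 poor,
#' 0.5-0.75 moderate, 0.75-0.9 good, at least 0.9 excellent.
#'
#' @param coefficient Numeric coefficient(s).
#' @param scale `"landis_koch"` or `"portney_watkins"`.
#' @return Character label(s).
#' @examples
#' benchmark_label(0.918, "landis_koch")
#' benchmark_label(0.986, "portney_watkins")
#' @export
benchmark_label <- function(coefficient,
                            scale = c("landis_koch", "portney_watkins")) {
  scale <- match.arg(scale)
  f <- function(x) {
    if (!is.finite(x)) return(NA_character_)
    if (scale == "landis_koch") {
      if (x < 0) "poor"
      else if (x <= 0.20) "slight"
      else if (x <= 0.40) "fair"
      else if (x <= 0.60) "moderate"
      else if (x <= 0.80) "substantial"
      else "almost perfect"
    } else {
      if (x < 0.5) "poor"
      else if (x < 0.75) "moderate"
      else if (x < 0.9) "good"
      else "excellent"
    }
  }
  vapply(coefficient, f, character(1))
}
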