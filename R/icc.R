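#' Intraclass correlation, two-way model, absolute agreement, single
#' measures
#'
#' For continuous measurements (the I3M maturity index) rated by k
#' observers on n subjects. Rows (subjects) and columns (raters) are
#' crossed factors; the absolute-agreement single-measure coefficient is
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C -
#'   MS_E)}}
#' so systematic rater offsets (MS_C) count against agreement. The
#' two-way mixed and two-way random formulations share this point
#' estimate; the mixed-model reading affects interpretation only.
#' Incomplete subject rows are dropped listwise (ANOVA balance) and the
#' dropped count is reported.
#'
#' The 95% CI is the standard F-based interval for this form and the
#' p-value comes from the F test of MS_R / MS_E.
#'
#' @param matrix A numeric units-by-raters matrix, or a continuous-method
#'   `rating_matrix`.
#' @return An object of class `icc_result`: `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `n_subjects`, `k_raters`, `n_dropped`, `ms_rows`,
#'   `ms_cols`, `ms_error`, `degenerate`.
#' @export
icc_absolute <- function(matrix) {
  x <- if (inherits(matrix, "rating_matrix")) matrix$values else
    as.matrix(matrix)
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  n_dropped <- sum(!complete)
  x <- x[complete, , drop = FALSE]
  n <- nrow(x)
  k <- ncol(x)
  if (k < 2L) stop("need at least two raters", call. = FALSE)
  if (n < 3L) stop("need at least three complete subject rows",
                   call. = FALSE)
  rmean <- rowMeans(x)
  cmean <- colMeans(x)
  gmean <- mean(x)
  ss_total <- sum((x - gmean)^2)
  if (ss_total <= 0) {
    return(structure(
      list(icc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           p_value = NA_real_, n_subjects = n, k_raters = k,
           n_dropped = n_dropped, ms_rows = 0, ms_cols = 0, ms_error = 0,
           degenerate = TRUE),
      class = "icc_result"))
  }
  msr <- k * sum((rmean - gmean)^2) / (n - 1)
  msc <- n * sum((cmean - gmean)^2) / (k - 1)
  sse <- sum((x - outer(rmean, rep(1, k)) -
                outer(rep(1, n), cmean) + gmean)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  # F test of subject variance
  if (mse > 0) {
    fstat <- msr / mse
    p_value <- stats::pf(fstat, n - 1, (n - 1) * (k - 1),
                         lower.tail = FALSE)
  } else {
    p_value <- 0
  }
  # McGraw & Wong F-based interval for ICC(A,1)
  alpha <- 0.05
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  ci_low <- ci_high <- NA_real_
  if (is.finite(a) && is.finite(b) && (a * msc + b * mse) > 0) {
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- stats::qf(1 - alpha / 2, n - 1, v)
    fu <- stats::qf(1 - alpha / 2, v, n - 1)
    denom_l <- fl * (k * msc + (k * n - k - n) * mse) + n * msr
    denom_u <- k * msc + (k * n - k - n) * mse + n * fu * msr
    ci_low <- n * (msr - fl * mse) / denom_l
    ci_high <- n * (fu * msr - mse) / denom_u
  } else if (icc == 1) {
    ci_low <- ci_high <- 1
  }
  ci_low <- max(-1, min(ci_low, icc, na.rm = TRUE))
  ci_high <- min(1, max(ci_high, icc, na.rm = TRUE))
  structure(
    list(icc = icc, ci_low = ci_low, ci_high = ci_high,
         p_value = p_value, n_subjects = n, k_raters = k,
         n_dropped = n_dropped, ms_rows = msr, ms_cols = msc,
         ms_error = mse, degenerate = FALSE),
    class = "icc_result"
  )
}

#' Intra-observer ICC from session pairs
#'
#' Absolute-agreement single-measure ICC on the n x 2 matrix of the two
#' sessions of one observer (a repeat offset between sessions lowers the
#' coefficient, as absolute agreement requires).
#'
#' @param pairs Output of [session_pairs()] (continuous method) or a
#'   two-column numeric matrix / data frame.
#' @return An `icc_result`.
#' @export
icc_intra <- function(pairs) {
  if (is.data.frame(pairs) && all(c("session1", "session2") %in%
                                  names(pairs))) {
    pairs <- cbind(as.numeric(pairs$session1),
                   as.numeric(pairs$session2))
  }
  icc_absolute(as.matrix(pairs))
}

#' @export
print.icc_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<ICC(A,1)> degenerate (zero total variance)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<ICC(A,1)> %.3f [%.3f; %.3f], p %s, n=%d subjects x %d raters (%d dropped)\n",
    x$icc, x$ci_low, x$ci_high,
    format.pval(x$p_value, digits = 3, eps = 1e-3),
    x$n_subjects, x$k_raters, x$n_dropped))
  cat(sprintf("  benchmark: %s (Portney-Watkins)\n",
              benchmark_label(x$icc, "portney_watkins")))
  invisible(x)
}
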