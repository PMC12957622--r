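#' Binarize a rating matrix to assessability (NA / not-NA)
#'
#' Every cell becomes one of the two categories `"notNA"` and `"NA"`; no
#' cell is missing in the output, so downstream agreement uses all cells
#' with no exclusion (e.g. 900 cells for a two-tooth method: 50 subjects
#' x 2 teeth x 9 observers).
#'
#' @param matrix A `rating_matrix` (ordinal or continuous).
#' @return A `rating_matrix` over the binary scheme `notNA`/`NA`.
#' @export
binarize_na <- function(matrix) {
  v <- matrix$values
  out <- matrix(ifelse(is.na(v), "NA", "notNA"), nrow(v), ncol(v),
                dimnames = dimnames(v))
  structure(
    list(values = out, units = matrix$units, raters = matrix$raters,
         scheme = staging_scheme(paste0(matrix$scheme$method_id, "_na"),
                                 c("notNA", "NA"),
                                 matrix$scheme$applicable_teeth)),
    class = "rating_matrix"
  )
}

#' Agreement on not-assessable (NA) responses
#'
#' Ratings are recoded to the binary assessability alphabet and
#' unweighted Gwet's AC1 is computed over all cells. AC1 is used because
#' NA responses are rare (prevalence typically under 5%), the exact
#' imbalance regime where kappa-type coefficients collapse despite high
#' raw concordance. Both binary categories are always kept in the weight
#' matrix (with zero NA anywhere, the chance agreement is 0 and AC1 is
#' exactly 1).
#'
#' @param matrix A `rating_matrix`.
#' @param prevalence_threshold Per-rater NA proportion above which the
#'   audit flag fires (reported descriptively, not a gate). Default 0.05.
#' @return A list of class `na_report`: `ac1` (an `agreement_result`),
#'   `na_count`, `na_proportion`, `per_rater_na_proportion`,
#'   `prevalence_flag`.
#' @export
na_agreement <- function(matrix, prevalence_threshold = 0.05) {
  if (ncol(matrix$values) < 2L) {
    stop("need at least two raters", call. = FALSE)
  }
  bin <- binarize_na(matrix)
  weights <- build_weights(c("notNA", "NA"), "identity")
  ac1 <- gwet_ac(bin, weights)
  ac1$method <- "Gwet AC1 (NA concordance)"
  isna <- is.na(matrix$values)
  per_rater <- colMeans(isna)
  names(per_rater) <- colnames(matrix$values)
  structure(
    list(
      ac1 = ac1,
      na_count = sum(isna),
      na_proportion = mean(isna),
      per_rater_na_proportion = per_rater,
      prevalence_flag = any(per_rater > prevalence_threshold)
    ),
    class = "na_report"
  )
}

#' @export
print.na_report <- function(x, ...) {
  cat(sprintf("<na_report> %d NA cells (%.1f%%); prevalence flag: %s\n",
              x$na_count, 100 * x$na_proportion,
              if (x$prevalence_flag) "YES (>5% for some rater)" else "no"))
  print(x$ac1)
  invisible(x)
}
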