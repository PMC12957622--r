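#' @keywords internal
"_PACKAGE"

RATING_COLUMNS <- c("subject_id", "observer_id", "session", "tooth",
                    "method", "value")

# Normalize the accepted NA markers ("NA", "N/A", "", case-insensitive) to R NA.
normalize_na <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- NA_character_
  miss <- !is.na(x) & toupper(trimws(x)) %in% c("NA", "N/A", "")
  x[miss] <- NA_character_
  x
}

new_rating_table <- function(df, schemes) {
  structure(df, class = c("rating_table", "data.frame"), schemes = schemes)
}

#' Read a long-format rating table
#'
#' One row per (subject, observer, session, tooth, method) holding an
#' ordinal stage label, a non-negative continuous value, or an NA marker
#' (`NA`, `N/A` or empty, case-insensitive). Stage labels are validated
#' against the method's scheme; offending rows are reported by number.
#'
#' @param path CSV file with header columns `subject_id`, `observer_id`,
#'   `session`, `tooth`, `method`, `value`.
#' @param schemes Named list of [staging_scheme()]s; defaults to
#'   [default_schemes()].
#' @return A `rating_table` (a validated data frame).
#' @seealso [write_ratings()], [pivot_to_matrix()]
#' @export
read_ratings <- function(path, schemes = default_schemes()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  missing_cols <- setdiff(RATING_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[RATING_COLUMNS]
  df$observer_id <- as.integer(df$observer_id)
  df$session <- as.integer(df$session)
  df$tooth <- as.integer(df$tooth)
  df$value <- normalize_na(df$value)
  validate_ratings(df, schemes)
}

#' Build a rating table from a data frame
#'
#' @param df Data frame with the rating-table columns (see
#'   [read_ratings()]).
#' @param schemes Named list of staging schemes.
#' @return A validated `rating_table`.
#' @export
as_rating_table <- function(df, schemes = default_schemes()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(RATING_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- df[RATING_COLUMNS]
  df$value <- normalize_na(as.character(df$value))
  validate_ratings(df, schemes)
}

validate_ratings <- function(df, schemes) {
  key <- do.call(paste, c(df[c("subject_id", "observer_id", "session",
                               "tooth", "method")], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (subject, observer, session, tooth, method) rows: ",
         paste(utils::head(which(duplicated(key)), 10L), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(df$method), names(schemes))
  if (length(unknown) > 0L) {
    stop("unknown method(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$session %in% c(1L, 2L))) {
    stop("session must be 1 or 2", call. = FALSE)
  }
  for (m in unique(df$method)) {
    sc <- schemes[[m]]
    rows <- which(df$method == m)
    bad_tooth <- rows[!(df$tooth[rows] %in% sc$applicable_teeth)]
    if (length(bad_tooth) > 0L) {
      stop(sprintf("method %s not applicable to tooth of rows: %s", m,
                   paste(utils::head(bad_tooth, 10L), collapse = ", ")),
           call. = FALSE)
    }
    v <- df$value[rows]
    obs <- !is.na(v)
    if (sc$is_continuous) {
      num <- suppressWarnings(as.numeric(v[obs]))
      bad <- rows[obs][is.na(num) | num < 0]
    } else {
      bad <- rows[obs][!(v[obs] %in% sc$categories)]
    }
    if (length(bad) > 0L) {
      stop(sprintf("invalid %s values in rows: %s", m,
                   paste(utils::head(bad, 10L), collapse = ", ")),
           call. = FALSE)
    }
  }
  row.names(df) <- NULL
  new_rating_table(df, schemes)
}

#' Write a rating table to CSV
#'
#' Missing values are serialized as the literal string `NA`, so that
#' `write_ratings()` followed by [read_ratings()] is lossless.
#'
#' @param table A `rating_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(table, path) {
  df <- as.data.frame(table)
  df$value[is.na(df$value)] <- "NA"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Chronological age in decimal years
#'
#' Exposure date minus date of birth, converted at 365.25 days per year
#' (the standard forensic convention).
#'
#' @param dob,exposure Dates (`Date` or ISO-8601 strings). Vectorized.
#' @return Decimal age in years.
#' @examples
#' chronological_age("2000-01-01", "2014-01-01")
#' @export
chronological_age <- function(dob, exposure) {
  dob <- as.Date(dob)
  exposure <- as.Date(exposure)
  if (any(exposure <= dob)) {
    stop("exposure date must be after date of birth", call. = FALSE)
  }
  as.numeric(exposure - dob) / 365.25
}

#' Pivot a rating table to a units-by-raters matrix
#'
#' The analysis unit is the (subject, tooth) pair: pooled ("Overall" or
#' per-jaw) coefficients stack the selected teeth as extra units, which
#' reproduces the study-design observation counts (e.g. 1800 cells for a
#' four-tooth method before NA exclusion). One column per observer; cells
#' are taken from the requested session.
#'
#' @param table A `rating_table`.
#' @param method Method label.
#' @param session Session number (inter-observer analyses use session 1).
#' @param pooling `"overall"`, `"maxillary"` or `"mandibular"`; ignored if
#'   `teeth` is given.
#' @param teeth Optional explicit FDI codes.
#' @return A `rating_matrix`: list with `values` (units x raters; character
#'   stages or numeric), `units` (subject/tooth data frame), `raters`, and
#'   `scheme`.
#' @export
pivot_to_matrix <- function(table, method, session = 1L,
                            pooling = "overall", teeth = NULL) {
  schemes <- attr(table, "schemes")
  sc <- schemes[[method]]
  if (is.null(sc)) stop("unknown method: ", method, call. = FALSE)
  teeth <- pooling_teeth(sc, pooling, teeth)
  df <- table[table$method == method & table$session == session &
                table$tooth %in% teeth, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("empty selection: no ratings for this method/session/teeth",
         call. = FALSE)
  }
  subjects <- sort(unique(df$subject_id))
  raters <- sort(unique(df$observer_id))
  units <- expand.grid(subject_id = subjects, tooth = teeth,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  units <- units[order(units$tooth, units$subject_id), , drop = FALSE]
  row.names(units) <- NULL
  ukey <- paste(units$subject_id, units$tooth, sep = "\r")
  values <- matrix(NA_character_, nrow(units), length(raters),
                   dimnames = list(ukey, as.character(raters)))
  values[cbind(
    match(paste(df$subject_id, df$tooth, sep = "\r"), ukey),
    match(df$observer_id, raters)
  )] <- df$value
  if (sc$is_continuous) {
    values <- matrix(as.numeric(values), nrow(values), ncol(values),
                     dimnames = dimnames(values))
  }
  structure(
    list(values = values, units = units, raters = raters, scheme = sc),
    class = "rating_matrix"
  )
}

#' @export
print.rating_matrix <- function(x, ...) {
  cat(sprintf("<rating_matrix> %s: %d units x %d raters, %d non-NA cells\n",
              x$scheme$method_id, nrow(x$values), ncol(x$values),
              sum(!is.na(x$values))))
  invisible(x)
}

#' Construct a rating matrix directly from a values matrix
#'
#' Convenience constructor (used by the simulator and for small worked
#' examples): rows are units, columns raters.
#'
#' @param values Character (ordinal) or numeric (continuous) matrix;
#'   `NA` marks missing ratings.
#' @param scheme The [staging_scheme()] the values belong to.
#' @return A `rating_matrix`.
#' @export
rating_matrix_from_values <- function(values, scheme) {
  if (is.null(rownames(values))) {
    rownames(values) <- seq_len(nrow(values))
  }
  structure(
    list(
      values = values,
      units = data.frame(subject_id = rownames(values),
                         tooth = NA_integer_),
      raters = seq_len(ncol(values)),
      scheme = scheme
    ),
    class = "rating_matrix"
  )
}

#' Session-1 / session-2 value pairs for one observer
#'
#' One pair per subject for a given (observer, method, tooth); pairs where
#' either session is NA are flagged for downstream exclusion (weighted
#' kappa and intra-observer ICC drop them).
#'
#' @param table A `rating_table` with both sessions present.
#' @param observer Observer id.
#' @param method Method label.
#' @param tooth FDI code.
#' @return Data frame with `subject_id`, `session1`, `session2`,
#'   `complete`.
#' @export
session_pairs <- function(table, observer, method, tooth) {
  df <- table[table$observer_id == observer & table$method == method &
                table$tooth == tooth, , drop = FALSE]
  s1 <- df[df$session == 1L, c("subject_id", "value")]
  s2 <- df[df$session == 2L, c("subject_id", "value")]
  if (nrow(s1) == 0L || nrow(s2) == 0L) {
    stop(sprintf("observer %s lacks a session for method %s tooth %s",
                 observer, method, tooth), call. = FALSE)
  }
  subjects <- sort(unique(c(s1$subject_id, s2$subject_id)))
  out <- data.frame(
    subject_id = subjects,
    session1 = s1$value[match(subjects, s1$subject_id)],
    session2 = s2$value[match(subjects, s2$subject_id)],
    stringsAsFactors = FALSE
  )
  out$complete <- !is.na(out$session1) & !is.na(out$session2)
  out
}
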