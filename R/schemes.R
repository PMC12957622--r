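#' Staging scheme definition
#'
#' A staging scheme describes one dental age estimation method: its ordered
#' stage alphabet (empty for continuous indices such as I3M) and the third
#' molars it can be applied to. The scheme is the unit over which the
#' conservative category-exclusion rule operates when weight matrices are
#' built.
#'
#' @param method_id Method label, e.g. `"DEM"`.
#' @param categories Character vector of ordered stage labels, or
#'   `character(0)` for a continuous method.
#' @param applicable_teeth Integer FDI codes the method applies to
#'   (subset of 18, 28, 38, 48).
#' @return An object of class `staging_scheme`.
#' @examples
#' staging_scheme("DEM", LETTERS[1:8], c(18L, 28L, 38L, 48L))
#' @export
staging_scheme <- function(method_id, categories, applicable_teeth) {
  categories <- as.character(categories)
  applicable_teeth <- as.integer(applicable_teeth)
  if (anyDuplicated(categories)) {
    stop("stage categories must be unique", call. = FALSE)
  }
  if (!all(applicable_teeth %in% c(18L, 28L, 38L, 48L))) {
    stop("applicable_teeth must be third molar FDI codes (18, 28, 38, 48)",
         call. = FALSE)
  }
  structure(
    list(
      method_id = as.character(method_id),
      categories = categories,
      is_continuous = length(categories) == 0L,
      applicable_teeth = applicable_teeth
    ),
    class = "staging_scheme"
  )
}

#' Default staging schemes of the four-method third molar study
#'
#' KUL: 7 ordinal stages, mandibular third molars only (the method has no
#' crown-development stages, so maxillary teeth are out of reach on
#' panoramic images). DEM: 8 stages A-H. GHK: 10 stages. I3M: continuous
#' third molar maturity index (open-apex width over tooth length), >= 0.
#'
#' @return Named list of [staging_scheme()] objects (`KUL`, `DEM`, `GHK`,
#'   `I3M`).
#' @export
default_schemes <- function() {
  list(
    KUL = staging_scheme("KUL", as.character(1:7), c(38L, 48L)),
    DEM = staging_scheme("DEM", LETTERS[1:8], c(18L, 28L, 38L, 48L)),
    GHK = staging_scheme("GHK", as.character(1:10), c(18L, 28L, 38L, 48L)),
    I3M = staging_scheme("I3M", character(0), c(38L, 48L))
  )
}

#' @export
print.staging_scheme <- function(x, ...) {
  cat(sprintf(
    "<staging_scheme> %s: %s; teeth %s\n", x$method_id,
    if (x$is_continuous) "continuous (>= 0)" else
      paste0(length(x$categories), " stages [",
             paste(x$categories, collapse = " "), "]"),
    paste(x$applicable_teeth, collapse = "/")
  ))
  invisible(x)
}

# Teeth selected by a pooling level, in FDI order.
pooling_teeth <- function(scheme, pooling = c("overall", "maxillary",
                                              "mandibular"), teeth = NULL) {
  if (!is.null(teeth)) {
    teeth <- as.integer(teeth)
    bad <- setdiff(teeth, scheme$applicable_teeth)
    if (length(bad) > 0L) {
      stop(sprintf("teeth %s not applicable to method %s",
                   paste(bad, collapse = ", "), scheme$method_id),
           call. = FALSE)
    }
    return(sort(teeth))
  }
  pooling <- match.arg(pooling)
  sel <- switch(pooling,
    overall = scheme$applicable_teeth,
    maxillary = intersect(c(18L, 28L), scheme$applicable_teeth),
    mandibular = intersect(c(38L, 48L), scheme$applicable_teeth)
  )
  if (length(sel) == 0L) {
    stop(sprintf("pooling '%s' selects no teeth for method %s",
                 pooling, scheme$method_id), call. = FALSE)
  }
  sort(sel)
}
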