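#' Categories actually observed in a rating matrix
#'
#' The conservative category-exclusion rule: stages that no observer used
#' anywhere in the analyzed table are dropped from the weight matrix. On
#' the reduced alphabet ordinal-style weights penalize a given stage
#' discrepancy more heavily than they would on the full alphabet.
#'
#' @param matrix A `rating_matrix` with an ordinal scheme.
#' @return Character vector of observed stage labels, in scheme order.
#' @export
observed_categories <- function(matrix) {
  sc <- matrix$scheme
  if (sc$is_continuous) {
    stop("observed_categories applies to ordinal methods only",
         call. = FALSE)
  }
  seen <- sc$categories[sc$categories %in% matrix$values]
  if (length(seen) == 0L) {
    stop("all cells are NA: no observed categories", call. = FALSE)
  }
  seen
}

#' Build an agreement weight matrix
#'
#' Weights live in \[0, 1\] with 1 on the diagonal. For Q ordered
#' categories at ordinal distance d = |k - l|:
#' \describe{
#'   \item{identity}{1 if d = 0, else 0 (nominal; yields AC1).}
#'   \item{linear}{1 - d / (Q - 1).}
#'   \item{quadratic}{1 - d^2 / (Q - 1)^2.}
#'   \item{ordinal}{1 - C(d + 1, 2) / C(Q, 2), the pairs-combination
#'     weighting recommended for ordinal stages (diagonal 1, extreme pair
#'     0).}
#' }
#'
#' @param categories Ordered character vector of stage labels (typically
#'   from [observed_categories()]).
#' @param kind One of `"identity"`, `"linear"`, `"quadratic"`,
#'   `"ordinal"`.
#' @return A Q x Q numeric matrix with `categories` as dimnames and
#'   attribute `kind`.
#' @examples
#' build_weights(LETTERS[1:5], "ordinal")
#' @export
build_weights <- function(categories,
                          kind = c("ordinal", "identity", "linear",
                                   "quadratic")) {
  kind <- match.arg(kind)
  categories <- as.character(categories)
  q <- length(categories)
  if (q < 1L) stop("need at least one category", call. = FALSE)
  if (q == 1L && kind != "identity") {
    stop("a single-category alphabet admits only identity weights",
         call. = FALSE)
  }
  d <- abs(outer(seq_len(q), seq_len(q), "-"))
  w <- switch(kind,
    identity = (d == 0) * 1,
    linear = 1 - d / (q - 1),
    quadratic = 1 - d^2 / (q - 1)^2,
    ordinal = 1 - choose(d + 1, 2) / choose(q, 2)
  )
  dimnames(w) <- list(categories, categories)
  attr(w, "kind") <- kind
  w
}
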