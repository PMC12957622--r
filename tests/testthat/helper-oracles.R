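# Independent brute-force implementations of the defining agreement
# formulas. These deliberately avoid the package's count-matrix algebra:
# observed agreement is enumerated over rater pairs, chance terms are
# assembled from explicit proportion vectors.

bf_pa <- function(values, W) {
  cats <- colnames(W)
  per_unit <- rep(NA_real_, nrow(values))
  for (i in seq_len(nrow(values))) {
    row <- values[i, ]
    row <- row[!is.na(row)]
    if (length(row) < 2) next
    s <- 0
    np <- 0
    for (a in seq_len(length(row) - 1)) {
      for (b in (a + 1):length(row)) {
        s <- s + W[match(row[a], cats), match(row[b], cats)]
        np <- np + 1
      }
    }
    per_unit[i] <- s / np
  }
  mean(per_unit, na.rm = TRUE)
}

# mean classification proportions over units with >= 1 rating
bf_pi <- function(values, cats) {
  rows <- which(rowSums(!is.na(values)) >= 1)
  pi_q <- rep(0, length(cats))
  for (i in rows) {
    row <- values[i, ]
    row <- row[!is.na(row)]
    for (q in seq_along(cats)) {
      pi_q[q] <- pi_q[q] + mean(row == cats[q])
    }
  }
  pi_q / length(rows)
}

bf_gwet <- function(values, W) {
  cats <- colnames(W)
  q <- length(cats)
  pa <- bf_pa(values, W)
  piq <- bf_pi(values, cats)
  pe <- sum(W) / (q * (q - 1)) * sum(piq * (1 - piq))
  (pa - pe) / (1 - pe)
}

bf_fleiss <- function(values, cats) {
  W <- diag(length(cats))
  dimnames(W) <- list(cats, cats)
  pa <- bf_pa(values, W)
  piq <- bf_pi(values, cats)
  pe <- sum(piq^2)
  (pa - pe) / (1 - pe)
}

bf_kappa_w <- function(x, y, W) {
  cats <- colnames(W)
  n <- length(x)
  po <- mean(W[cbind(match(x, cats), match(y, cats))])
  pk <- vapply(cats, function(c) mean(x == c), numeric(1))
  pl <- vapply(cats, function(c) mean(y == c), numeric(1))
  pe <- 0
  for (k in seq_along(cats)) {
    for (l in seq_along(cats)) {
      pe <- pe + W[k, l] * pk[k] * pl[l]
    }
  }
  (po - pe) / (1 - pe)
}

# brute-force ordinal weight from its definition: pairs of categories
# within distance d, relative to all category pairs
bf_ordinal_weight <- function(d, q) {
  1 - (choose(d + 1, 2) / choose(q, 2))
}

# leave-one-unit-out jackknife standard error of a Gwet-type coefficient
jackknife_se <- function(values, W, pe_type = "gwet") {
  n <- nrow(values)
  th <- vapply(seq_len(n), function(i) {
    cc <- dentagree:::count_matrix(values[-i, , drop = FALSE],
                                   colnames(W))
    dentagree:::agreement_from_counts(cc, W, pe_type)$coefficient
  }, numeric(1))
  sqrt((n - 1) / n * sum((th - mean(th))^2))
}

scheme_for <- function(cats) {
  staging_scheme("TST", cats, c(18L, 28L, 38L, 48L))
}

matrix_for <- function(values, cats) {
  rating_matrix_from_values(values, scheme_for(cats))
}

# random multi-rater matrix with missing cells
random_rating_values <- function(n_units, n_raters, cats,
                                 na_frac = 0.1) {
  vals <- matrix(sample(cats, n_units * n_raters, replace = TRUE),
                 n_units, n_raters)
  nna <- round(na_frac * length(vals))
  if (nna > 0) vals[sample(length(vals), nna)] <- NA
  vals
}

# small two-session rating table used by study_data tests
toy_rating_table <- function() {
  grid <- expand.grid(subject_id = sprintf("S%02d", 1:5),
                      observer_id = 1:3, session = 1:2,
                      tooth = c(38L, 48L), stringsAsFactors = FALSE)
  grid$method <- "DEM"
  set.seed(99)
  grid$value <- sample(c(LETTERS[4:8], NA), nrow(grid), replace = TRUE)
  as_rating_table(grid)
}
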