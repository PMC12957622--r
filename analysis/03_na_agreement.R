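#!/usr/bin/env Rscript
# Step 3 — agreement on not-assessable (NA) responses.
#
# Ratings are recoded to the binary assessability alphabet and
# unweighted Gwet's AC1 is computed over all session-1 cells (no
# exclusion: binarization removes missingness), with the 5% per-rater
# prevalence audit. Requires step 01.

suppressMessages(library(dentagree))

ratings <- read_ratings("results/ratings.csv")

rows <- list()
for (m in c("KUL", "DEM", "GHK", "I3M")) {
  sc <- attr(ratings, "schemes")[[m]]
  poolings <- if (length(sc$applicable_teeth) == 4L) {
    c(Overall = "overall", Maxillary = "maxillary",
      Mandibular = "mandibular")
  } else {
    c(Overall = "overall")
  }
  for (nm in names(poolings)) {
    mat <- pivot_to_matrix(ratings, m, session = 1L,
                           pooling = poolings[[nm]])
    rep <- na_agreement(mat)
    rows[[length(rows) + 1L]] <- data.frame(
      method = m, level = nm,
      ac1 = round(rep$ac1$coefficient, 3),
      ci_low = round(rep$ac1$ci_low, 3),
      ci_high = round(rep$ac1$ci_high, 3),
      n_observations = length(mat$values),
      na_count = rep$na_count,
      na_pct = round(100 * rep$na_proportion, 1),
      prevalence_flag = rep$prevalence_flag)
    message(sprintf(
      "  %-4s %-10s AC1 %.3f [%.3f; %.3f]  cells=%d  NA=%d (%.1f%%)%s",
      m, nm, rep$ac1$coefficient, rep$ac1$ci_low, rep$ac1$ci_high,
      length(mat$values), rep$na_count, 100 * rep$na_proportion,
      if (rep$prevalence_flag) "  [>5% for some rater]" else ""))
  }
}
na_table <- do.call(rbind, rows)
utils::write.csv(na_table, "results/table_na_agreement.csv",
                 row.names = FALSE)
message("wrote results/table_na_agreement.csv")
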