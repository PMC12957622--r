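#!/usr/bin/env Rscript
# Step 2 — intra- and inter-observer reliability tables.
#
# Intra-observer: weighted Cohen's kappa (ordinal weights) per observer,
# method and tooth from the session-1 / session-2 pairs; absolute-
# agreement ICC for the continuous I3M. Inter-observer (session 1
# only): Gwet's AC2 with ordinal weights for the staging methods at
# Overall / per-jaw / per-tooth pooling, ICC for I3M. Requires step 01.

suppressMessages(library(dentagree))

ratings <- read_ratings("results/ratings.csv")
report <- run_study_analysis(ratings, weights_kind = "ordinal")
format_tables(report, "results", formats = c("csv", "markdown", "json"))

message("inter-observer reliability (Overall rows):")
for (m in names(report$inter)) {
  r <- report$inter[[m]][report$inter[[m]]$level == "Overall", ]
  message(sprintf("  %-4s %-28s %.3f [%.3f; %.3f]  n=%d  %s", m,
                  r$statistic, r$coefficient, r$ci_low, r$ci_high,
                  r$n_observations, r$benchmark))
}
intra <- report$intra
message(sprintf(
  "intra-observer coefficients: min %.3f, median %.3f, max %.3f over %d rows",
  min(intra$coefficient), stats::median(intra$coefficient),
  max(intra$coefficient), nrow(intra)))
message(sprintf(
  "maxillary vs mandibular AC2 (DEM): %.3f vs %.3f",
  report$inter$DEM$coefficient[report$inter$DEM$level == "Maxillary"],
  report$inter$DEM$coefficient[report$inter$DEM$level == "Mandibular"]))
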