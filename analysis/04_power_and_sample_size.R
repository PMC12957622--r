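#!/usr/bin/env Rscript
# Step 4 — sample-size planning calculations.
#
# (a) Bonett's closed-form precision sample size for the ICC arm
#     (expected ICC 0.8, 9 raters, 95% CI half-width 0.1).
# (b) Simulation-based power of the one-sided Gwet AC2 test (true mean
#     0.6 vs null 0.4, alpha 0.05, ordinal weights) for 9 raters under
#     7 / 8 / 10 categories and uniform / skew-low / skew-high
#     marginals, extracting the minimum n for 80% power per condition.
# (c) The generic simulation-based CI-precision search, the stand-in
#     for closed-form multi-rater kappa planning.
#
# 2000 power replicates per grid point here keep this driver around a
# minute; scripts/acceptance.R runs the same search at higher
# replication.

suppressMessages(library(dentagree))
dir.create("results", showWarnings = FALSE)

n_icc <- bonett_icc_n(rho_plan = 0.8, k_raters = 9, halfwidth = 0.1,
                      confidence = 0.95)
message(sprintf("(a) Bonett ICC precision sample size: %d subjects",
                n_icc))

pg <- min_n_for_power(reps = 2000L, calib_reps = 2000L, seed = 73L)
print(pg)
utils::write.csv(pg$grid, "results/power_grid.csv", row.names = FALSE)
utils::write.csv(pg$min_n, "results/power_min_n.csv",
                 row.names = FALSE)

prec <- precision_n_simulated("kappa", expected = 0.8, halfwidth = 0.1,
                              n_raters = 6, n_categories = 5,
                              marginal = "uniform",
                              n_grid = c(10L, 25L, 50L, 100L, 200L),
                              reps = 300L, seed = 73L)
message(sprintf(
  "(c) precision search (Fleiss-type kappa, 6 raters, 5 categories, expected 0.8, half-width 0.1): n = %s",
  prec$n))

jsonlite::write_json(
  list(bonett_icc_n = n_icc,
       ac2_power_min_n = pg$recommended_n,
       kappa_precision_n = prec$n),
  "results/sample_size.json", auto_unbox = TRUE, digits = NA)
message("wrote results/power_grid.csv, results/power_min_n.csv, results/sample_size.json")
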