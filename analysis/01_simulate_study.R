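#!/usr/bin/env Rscript
# Step 1 — generate the synthetic multi-observer staging study.
#
# No raw rating data is distributed with the original study, so the
# whole workflow runs on a synthetic stand-in with the same design:
# 50 subjects (14-23.99 y, 19 M / 31 F), 9 observers, 2 sessions, four
# third molars, four methods (KUL / DEM / GHK staging, continuous I3M),
# with per-tooth stage marginals and NA rates matching the published
# descriptive table, and writes the descriptive table back out from the
# generated data.

suppressMessages(library(dentagree))

seed <- 20251L
dir.create("results", showWarnings = FALSE)

cfg <- study_config(seed = seed)
study <- generate_study(cfg)

write_ratings(study$ratings, "results/ratings.csv")
utils::write.csv(study$subjects, "results/subjects.csv",
                 row.names = FALSE)

desc <- describe_ratings(study$ratings, session = 1L)
utils::write.csv(desc$stages, "results/table_descriptives_stages.csv",
                 row.names = FALSE)
utils::write.csv(desc$continuous,
                 "results/table_descriptives_i3m.csv",
                 row.names = FALSE)

message(sprintf("generated %d rating records for %d subjects (seed %d)",
                nrow(study$ratings), nrow(study$subjects), seed))
i3m <- desc$continuous
message(sprintf(
  "I3M session-1 medians: FDI 38 %.2f (%.2f-%.2f), FDI 48 %.2f (%.2f-%.2f)",
  i3m$median[1], i3m$q1[1], i3m$q3[1],
  i3m$median[2], i3m$q1[2], i3m$q3[2]))
message(sprintf("age range %.1f-%.1f y; NA cells: %d",
                min(study$subjects$chronological_age),
                max(study$subjects$chronological_age),
                sum(is.na(study$ratings$value))))
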