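#!/usr/bin/env Rscript
# Stage 2: residual-based quality control.
#
# Screens every simulated cohort with the age + sex + age-by-sex adjustment
# GAMM and the 2-SD between-/within-subject residual rules, and writes the
# flag tables. Flags mark records for review; nothing is dropped here (the
# generating model contains no true outliers, so flags reflect the expected
# false-positive rate of the rules, ~4.6% per test).

library(braintraj)

regions <- c("cortical_gm", "white_matter", "pallidum", "caudate")
dir.create("results/qc", recursive = TRUE, showWarnings = FALSE)

for (r in regions) {
  d <- read_long_table(file.path("results/cohorts", paste0(r, ".csv")))
  rep_r <- detect_outliers(d, r, threshold_sd = 2)
  utils::write.csv(rep_r$flags, file.path("results/qc", paste0(r, "_flags.csv")),
                   row.names = FALSE)
  cat(sprintf("%-13s %2d between-subject, %2d within-subject flags (%.1f%% of records)\n",
              r, rep_r$n_between, rep_r$n_within,
              100 * rep_r$n_within / rep_r$n_obs))
}
cat("flag tables written to results/qc/\n")
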