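#!/usr/bin/env Rscript
# Stage 5: individual differences and baseline-change correlations.
#
# Summarizes the per-subject empirical-Bayes growth scalars written by
# stage 4 (inflection point for logistic regions, slope for linear ones):
# min/max/range, per-sex means, density quantiles, out-of-range timing
# flags, and the Pearson correlation between each region's baseline
# parameter (upper or lower asymptote / intercept) and the absolute change
# parameter (|hill| or |slope|).

library(braintraj)

regions <- c("cortical_gm", "white_matter", "pallidum", "caudate")
dir.create("results", showWarnings = FALSE)

summ_rows <- list(); cor_rows <- list()
for (r in regions) {
  ind <- utils::read.csv(file.path("results/nlmm", paste0(r, "_individual.csv")),
                         stringsAsFactors = FALSE)
  scalar <- if ("inflection" %in% names(ind)) "inflection" else "b"
  attr(ind, "scalar") <- scalar
  class(ind) <- c("individual_fit", "data.frame")
  s <- summarize_individual_differences(ind)
  d <- read_long_table(file.path("results/cohorts", paste0(r, ".csv")))
  oor <- if (scalar == "inflection") flag_out_of_range(ind, range(d$age)) else ind[0, ]
  summ_rows[[r]] <- data.frame(
    region = r, scalar = scalar, min = s$min, max = s$max, range = s$range,
    mean = s$mean, female_mean = s$mean_by_sex[["female"]],
    male_mean = s$mean_by_sex[["male"]], n_out_of_range = nrow(oor))
  cat(sprintf("%-13s %s range %.2f-%.2f (span %.2f); F %.2f vs M %.2f; %d out-of-range\n",
              r, scalar, s$min, s$max, s$range,
              s$mean_by_sex[["female"]], s$mean_by_sex[["male"]], nrow(oor)))

  baseline <- switch(r, cortical_gm = "a_upper", white_matter = "a_lower",
                     pallidum = "a_lower", caudate = "a")
  change <- if (scalar == "inflection") "hill" else "b"
  ct <- correlate_baseline_change(ind, baseline, change)
  cor_rows[[r]] <- data.frame(region = r, baseline = baseline, change = change,
                              r = ct$r, df = ct$df, p = ct$p)
  cat(sprintf("              baseline %s vs |%s|: r(%d) = %.2f, p = %.3g\n",
              baseline, change, ct$df, ct$r, ct$p))
}
utils::write.csv(do.call(rbind, summ_rows), "results/individual_summary.csv",
                 row.names = FALSE)
utils::write.csv(do.call(rbind, cor_rows), "results/baseline_change.csv",
                 row.names = FALSE)
cat("summaries written to results/\n")
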