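#!/usr/bin/env Rscript
# Stage 3: data-driven trajectory shape.
#
# Fits the REML penalized-smooth mixed model (k = 7 age smooth for females,
# male difference smooth, sex intercept contrast, subject random intercept)
# per region, classifies each age smooth by its effective degrees of
# freedom, and writes a combined smooth/parametric summary table.

library(braintraj)

regions <- c("cortical_gm", "white_matter", "pallidum", "caudate")
dir.create("results", showWarnings = FALSE)

rows <- list()
for (r in regions) {
  d <- read_long_table(file.path("results/cohorts", paste0(r, ".csv")))
  g <- fit_gamm(d, r)
  shape <- classify_shape(g, "age")
  s1 <- smooth_significance(g, "age")
  s2 <- smooth_significance(g, "age:sex")
  sexrow <- g$parametric_table[grep("^sexo", rownames(g$parametric_table)), ]
  rows[[r]] <- data.frame(
    region = r,
    sex_estimate = sexrow$estimate, sex_se = sexrow$se, sex_p = sexrow$p,
    s_age_edf = s1[["edf"]], s_age_F = s1[["F"]], s_age_p = s1[["p"]],
    s_agesex_edf = s2[["edf"]], s_agesex_F = s2[["F"]], s_agesex_p = s2[["p"]],
    classification = shape$classification
  )
  cat(sprintf("%-13s s(age) edf %.2f -> %s; age-by-sex edf %.2f (p = %.3g)\n",
              r, s1[["edf"]], shape$classification, s2[["edf"]], s2[["p"]]))
}
tab <- do.call(rbind, rows)
utils::write.csv(tab, "results/gamm_summary.csv", row.names = FALSE)
cat("GAMM summary written to results/gamm_summary.csv\n")
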