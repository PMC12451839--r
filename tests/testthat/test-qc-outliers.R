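test_that("injected outliers are flagged by the matching rule", {
  sim <- sim_caudate(3)
  d <- sim$data

  base <- detect_outliers(d, "caudate")
  sd_w <- base$residual_sd_within
  sd_b <- base$subject_mean_sd

  # within-subject positive control: one record perturbed by +6 within-SDs
  d_w <- d
  counts <- table(d$subject_id)
  vict_subj <- names(counts)[counts >= 6][10]
  victim <- which(d_w$subject_id == vict_subj)[3]
  d_w$volume[victim] <- d_w$volume[victim] + 6 * sd_w
  rep_w <- detect_outliers(long_volumes(as.data.frame(d_w)), "caudate")
  hit <- rep_w$flags[rep_w$flags$kind == "within_subject" &
                       rep_w$flags$subject_id == vict_subj &
                       rep_w$flags$wave == d$wave[victim], ]
  expect_equal(nrow(hit), 1)
  expect_gte(abs(hit$z), 2)

  # between-subject positive control: one subject's whole series shifted
  d_b <- d
  shift_subj <- names(counts)[counts >= 6][20]
  rows <- d_b$subject_id == shift_subj
  d_b$volume[rows] <- d_b$volume[rows] + 5 * sd_b
  rep_b <- detect_outliers(long_volumes(as.data.frame(d_b)), "caudate")
  expect_true(shift_subj %in%
                rep_b$flags$subject_id[rep_b$flags$kind == "between_subject"])

  # exclusion mode drops exactly the flagged records
  rep_x <- detect_outliers(long_volumes(as.data.frame(d_b)), "caudate",
                           exclude = TRUE)
  expect_false(shift_subj %in% rep_x$cleaned$subject_id)
  expect_lt(nrow(rep_x$cleaned), nrow(d_b))
})

test_that("noise-free well-specified data produces no flags", {
  m <- preset("caudate")
  m$between_sd[] <- 0
  m$residual_sd <- 1e-8
  sim <- simulate_cohort(design_config(n_subjects = 30, seed = 11), m, "caudate")
  rep0 <- detect_outliers(sim$data, "caudate")
  expect_equal(nrow(rep0$flags), 0)
})

test_that("flags are invariant under volume rescaling", {
  d <- sim_caudate(3)$data
  r1 <- detect_outliers(d, "caudate")
  d2 <- d
  d2$volume <- d2$volume / 100
  r2 <- detect_outliers(long_volumes(as.data.frame(d2)), "caudate")
  key <- function(r) paste(r$flags$subject_id, r$flags$wave, r$flags$kind)
  expect_setequal(key(r1), key(r2))
  expect_equal(r1$flags$z[order(key(r1))], r2$flags$z[order(key(r2))],
               tolerance = 1e-4)
})

test_that("single-observation subjects are skipped by the within rule", {
  d <- as.data.frame(sim_caudate(3)$data)
  extra <- d[1, ]
  extra$subject_id <- "S999"
  d <- long_volumes(rbind(d, extra))
  rep1 <- detect_outliers(d, "caudate")
  expect_gte(rep1$n_singleton_skipped, 1)
  expect_false("S999" %in%
                 rep1$flags$subject_id[rep1$flags$kind == "within_subject"])
})
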