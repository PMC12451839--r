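test_that("design statistics converge to the configured study profile", {
  big <- sample_design(design_config(n_subjects = 4000, seed = 99))
  scans <- table(big$subject_id)
  # baseline always kept + 11 follow-ups each retained w.p. 0.69
  expect_equal(mean(scans), 1 + 11 * 0.69, tolerance = 0.02)
  expect_true(min(big$age) >= 7.6 - 0.3 && min(big$age) < 7.9)
  # oldest possible: max baseline 12.90 + 8.5 span + jitter
  expect_gt(max(big$age), 21.0)
  expect_lt(max(big$age), 21.7)
  subj <- unique(big[c("subject_id", "sex")])
  expect_equal(mean(subj$sex == "female"), 53 / 90, tolerance = 0.02)
  # euler truncated at zero, centred near -150
  expect_true(all(big$euler <= 0))
  expect_equal(mean(big$euler), -155, tolerance = 0.05)
  # five ordinal software epochs keyed to calendar position
  expect_setequal(unique(big$software), paste0("sw", 1:5))
  expect_true(all(big$software[big$wave == 1] == "sw1"))
  expect_true(all(big$software[big$wave == 12] == "sw5"))
})

test_that("a noise-free single-subject design hits the canonical schedule", {
  cfg <- design_config(n_subjects = 1, visit_missing_prob = 0,
                       timing_jitter_sd = 0, seed = 3)
  d <- sample_design(cfg)
  expect_equal(nrow(d), 12)
  expect_equal(d$age - d$age[1],
               c(0, 0.5, 1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5, 5.5, 8.5))
})

test_that("simulation is seed-deterministic and honours the noise-free limit", {
  a <- simulate_cohort(design_config(seed = 5), preset("caudate"), "caudate")
  b <- simulate_cohort(design_config(seed = 5), preset("caudate"), "caudate")
  expect_identical(a$data$volume, b$data$volume)
  expect_identical(a$truth$subjects, b$truth$subjects)

  m <- preset("cortical_gm")
  m$between_sd[] <- 0
  m$residual_sd <- 1e-9
  sim <- simulate_cohort(design_config(seed = 5), m, "cortical_gm")
  mu <- eval_logistic(sim$data$age, m$params[["a_lower"]], m$params[["a_upper"]],
                      m$params[["inflection"]], m$params[["hill"]])
  expect_equal(sim$data$volume, mu, tolerance = 1e-6)
  # cortical grey matter declines from ~6100 to ~5100 rescaled units
  expect_equal(eval_logistic(8, m$params[[1]], m$params[[2]], m$params[[3]], m$params[[4]]),
               6077, tolerance = 5 / 6077)
  expect_equal(eval_logistic(21, m$params[[1]], m$params[[2]], m$params[[3]], m$params[[4]]),
               5192, tolerance = 5 / 5192)
})

test_that("presets carry the published group estimates and conventions", {
  expect_equal(preset("cortical_gm")$params[["inflection"]], 14.52)
  expect_equal(preset("caudate")$params[["b"]], -31.00)
  expect_identical(preset("pallidum")$fun, "logistic")
  expect_identical(preset("hippocampus")$fun, "linear")
  expect_true(preset("cortical_gm")$rescaled)
  expect_false(preset("pallidum")$rescaled)
  # default: no covariate effects in generation; "paper" switches them on
  expect_true(all(preset("cortical_gm")$sex_effects == 0))
  expect_equal(preset("cortical_gm", effects = "paper")$sex_effects[["inflection"]],
               4.92)
  expect_equal(preset("cortical_gm", effects = "paper")$motion_effect, 0.01)
  # variance-component conventions: 5% between-subject, 2% residual
  p <- preset("pallidum")
  expect_equal(unname(p$between_sd), unname(abs(p$params) * 0.05))
  expect_equal(p$residual_sd, 0.02 * (1741.55 + 2154.30) / 2)
  expect_error(preset("cerebellum"), "valid names")
})

test_that("sex effects and motion effects enter generation as specified", {
  m <- preset("cortical_gm", effects = "paper")
  m$between_sd[] <- 0
  m$residual_sd <- 1e-9
  sim <- simulate_cohort(design_config(seed = 8), m, "cortical_gm")
  tr <- sim$truth$subjects
  males <- tr$sex == "male"
  expect_equal(unique(tr$inflection[males] - 14.52), 4.92)
  expect_equal(unique(tr$inflection[!males] - 14.52), 0)
  # hill carries the motion term: population + sex + 0.01 * subject-mean euler
  expect_equal(tr$hill, -5.94 + 2.10 * males + 0.01 * tr$mean_euler,
               tolerance = 1e-12)
})

test_that("degenerate inflection draws are resampled with a warning", {
  m <- preset("pallidum")
  m$params[["inflection"]] <- 0.1
  m$between_sd[["inflection"]] <- 3
  expect_warning(
    sim <- simulate_cohort(design_config(n_subjects = 40, seed = 2), m, "pallidum"),
    "resampled")
  expect_true(all(sim$truth$subjects$inflection > 0))
})
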