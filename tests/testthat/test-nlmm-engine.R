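test_that("noise-free linear data is recovered essentially exactly", {
  m <- preset("caudate")
  m$between_sd[] <- 0
  m$residual_sd <- 1e-6
  sim <- simulate_cohort(design_config(n_subjects = 20, seed = 4), m, "caudate")
  fit <- fit_nlmm(sim$data, "caudate", structural_spec("linear"), seed = 1)
  expect_equal(fit$estimates[["a"]], 4673.60, tolerance = 1e-4)
  expect_equal(fit$estimates[["b"]], -31.00, tolerance = 1e-4)
})

test_that("the linear path agrees with an independent mixed-model solver", {
  skip_if_not_installed("lme4")
  m <- preset("caudate")
  m$between_sd <- c(a = 0.05 * 4673.60, b = 0.05 * 31)
  m$residual_sd <- 150
  sim <- simulate_cohort(design_config(seed = 1), m, "caudate")
  fit <- fit_nlmm(sim$data, "caudate", structural_spec("linear"), seed = 1)
  lf <- lme4::lmer(volume ~ age + (1 + age || subject_id),
                   data = as.data.frame(sim$data), REML = FALSE)
  expect_equal(unname(fit$estimates),
               unname(lme4::fixef(lf)), tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(lf)), tolerance = 1e-6)

  # with a sex covariate on both parameters
  fit2 <- fit_nlmm(sim$data, "caudate",
                   structural_spec("linear",
                                   covariates = covariate_map(c("a", "b"),
                                                              c("sex", "sex"))),
                   seed = 1)
  lf2 <- lme4::lmer(volume ~ age * sex + (1 + age || subject_id),
                    data = as.data.frame(sim$data), REML = FALSE)
  expect_equal(fit2$loglik, as.numeric(logLik(lf2)), tolerance = 1e-6)
  fe2 <- lme4::fixef(lf2)
  expect_equal(fit2$estimates[["sex.a"]], unname(fe2["sexmale"]), tolerance = 1e-3)
  expect_equal(fit2$estimates[["sex.b"]], unname(fe2["age:sexmale"]), tolerance = 1e-3)
})

test_that("information criteria follow the stated formulas", {
  expect_equal(unname(information_criteria(-100, k = 4, n_subjects = 90)),
               c(-2 * -100 + 2 * 4, -2 * -100 + 4 * log(90)))
  expect_equal(unname(information_criteria(-100, k = 0, n_subjects = 90)),
               c(200, 200))
  fit <- fit_nlmm(toy_linear_data(), "caudate", structural_spec("linear"), seed = 1)
  ic <- information_criteria(fit)
  expect_equal(unname(ic["aic"]), -2 * fit$loglik + 2 * fit$k)
  expect_equal(unname(ic["bic"]), -2 * fit$loglik + fit$k * log(fit$n_subjects))
  expect_equal(fit$k, 2 + 2 + 1)  # fixed effects + RE variances + residual
})

test_that("a nested linear model never has higher log-likelihood", {
  d <- sim_caudate(1)$data
  f0 <- fit_nlmm(d, "caudate", structural_spec("linear"), seed = 1)
  f1 <- fit_nlmm(d, "caudate",
                 structural_spec("linear", covariates = covariate_map("b", "sex")),
                 seed = 1)
  expect_gte(f1$loglik, f0$loglik - 1e-6)
})

test_that("cv_percent reproduces published precision values and gates strictly", {
  expect_equal(round(cv_percent(5089.72, 57.63), 2), 1.13)
  expect_equal(round(cv_percent(-5.94, 0.72), 2), 12.12)
  expect_equal(cv_percent(10, 2), 20)
  expect_false(cv_gate(10, 2))       # boundary fails the strict gate
  expect_true(cv_gate(10, 1.9))
  expect_true(is.na(cv_percent(0, 1)))
  expect_false(cv_gate(0, 1))
})

test_that("logistic population fit recovers the generating curve with precise CVs", {
  fit <- fit_cortical(1)
  tr <- preset("cortical_gm")$params
  expect_equal(fit$estimates[["inflection"]], tr[["inflection"]],
               tolerance = 0.05)
  expect_equal(fit$estimates[["a_lower"]], tr[["a_lower"]], tolerance = 0.02)
  expect_equal(fit$estimates[["a_upper"]], tr[["a_upper"]], tolerance = 0.02)
  # structural parameters are estimated with good precision (CV < 20%)
  expect_true(all(cv_gate(fit$estimates, fit$standard_errors)))
  expect_true(fit$convergence$converged)
  expect_equal(fit$residual_sd, preset("cortical_gm")$residual_sd,
               tolerance = 0.1)
  # same seed reproduces the fit exactly
  fit_b <- fit_nlmm(sim_cortical(1)$data, "cortical_gm",
                    structural_spec("logistic"), seed = 501,
                    control = test_control(compute_se = TRUE))
  expect_identical(fit$estimates, fit_b$estimates)
})

test_that("empirical-Bayes estimates shrink, track the truth, and order correctly", {
  # generator with a wide spread of individual inflections (SD 1.5 y) so the
  # per-subject timing is actually identifiable from ~8 visits
  m <- preset("cortical_gm")
  m$between_sd["inflection"] <- 1.5
  sim <- cached("cgm_wide",
                simulate_cohort(design_config(seed = 7), m, "cortical_gm"))
  fit <- cached("fit_cgm_wide",
                fit_nlmm(sim$data, "cortical_gm", structural_spec("logistic"),
                         seed = 77, control = test_control()))
  ind <- individual_estimates(fit, sim$data)
  expect_equal(nrow(ind), 90)
  tr <- sim$truth$subjects
  # individual inflections correlate with the generating subject truths
  ord <- match(ind$subject_id, tr$subject_id)
  expect_gt(cor(ind$inflection, tr$inflection[ord]), 0.5)
  # a subject simulated well above the population mean lands above the
  # population estimate
  hi <- tr$subject_id[which.max(tr$inflection)]
  expect_gt(ind$inflection[ind$subject_id == hi],
            fit$estimates[["inflection"]])
  # shrinkage: the EB spread does not exceed the generating spread wildly
  expect_lt(sd(ind$inflection), 2 * sd(tr$inflection))

  # full-shrinkage limit: no between-subject variance in the generator
  m0 <- preset("caudate"); m0$between_sd[] <- 1e-8
  sim0 <- simulate_cohort(design_config(n_subjects = 20, seed = 9), m0, "caudate")
  f0 <- fit_nlmm(sim0$data, "caudate", structural_spec("linear"), seed = 2)
  i0 <- individual_estimates(f0, sim0$data)
  expect_equal(i0$derived, rep(f0$estimates[["b"]], 20), tolerance = 1e-2)
})

test_that("predicted-observed diagnostics separate good fits from misfits", {
  fit <- fit_cortical(1)
  sim <- sim_cortical(1)
  pv <- predicted_vs_observed(fit, sim$data)
  expect_equal(unname(pv$individual_line["slope"]), 1, tolerance = 0.05)
  # fitting a linear function to logistic data departs from the identity
  flin <- fit_nlmm(sim$data, "cortical_gm", structural_spec("linear"), seed = 3)
  pv_bad <- predicted_vs_observed(flin, sim$data)
  # the true model predicts the observations better than the misfit
  mse <- function(pv) mean((pv$table$observed - pv$table$individual)^2)
  expect_lt(mse(pv), mse(pv_bad))
  expect_true(pv$clustering_index >= 0 && pv$clustering_index <= 1)
})

test_that("out-of-range timing estimates are flagged with observation counts", {
  ind <- data.frame(subject_id = c("A", "B", "C"), sex = "female",
                    derived = c(14.2, 5.65, 16.0), n_obs = c(9L, 3L, 8L))
  class(ind) <- c("individual_fit", "data.frame")
  flags <- flag_out_of_range(ind, c(7.6, 21.6))
  expect_equal(flags$subject_id, "B")
  expect_equal(flags$n_obs, 3L)
  expect_equal(nrow(flag_out_of_range(ind, c(5, 22))), 0)
})
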