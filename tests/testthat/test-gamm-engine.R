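test_that("the spline basis penalty vanishes exactly on constant and linear fits", {
  set.seed(21)
  ages <- runif(120, 7.6, 21.6)
  bb <- build_basis(ages, k = 7)
  expect_equal(dim(bb$X), c(120, 7))
  # coefficients reproducing a constant / linear function are penalty-free
  for (target in list(rep(2, 120), 3 + 0.5 * ages)) {
    cf <- qr.solve(bb$X, target)
    expect_lt(as.numeric(t(cf) %*% bb$S %*% cf), 1e-8)
  }
  # a genuinely curved fit pays a positive penalty
  cf_curv <- qr.coef(qr(bb$X), sin(ages))
  expect_gt(as.numeric(t(cf_curv) %*% bb$S %*% cf_curv), 1e-4)
  expect_error(build_basis(rep(10, 50), k = 7), "distinct ages")
})

test_that("shape classification follows the edf bands", {
  fake <- list(smooth_table = data.frame(edf = c(1.004, 1.7, 5.55),
                                         ref_df = c(1, 1.9, 5.6),
                                         F = c(1, 2, 100), p = c(0.3, 0.1, 0),
                                         row.names = c("s(age)", "s(x2)", "s(x3)")))
  class(fake) <- "smooth_fit"
  expect_equal(classify_shape(fake, "s(age)")$classification, "linear")
  expect_equal(classify_shape(fake, "s(x2)")$classification, "weakly nonlinear")
  expect_equal(classify_shape(fake, "s(x3)")$classification, "nonlinear")
})

test_that("edf recovers linear vs nonlinear generating shapes", {
  # straight-line truth: reference age smooth collapses to its null space
  g_lin <- cached("gamm_caudate1", fit_gamm(sim_caudate(1)$data, "caudate"))
  expect_lt(classify_shape(g_lin, "age")$edf, 1.3)
  expect_equal(classify_shape(g_lin, "age")$classification, "linear")

  # S-shaped logistic truth: clearly nonlinear and overwhelmingly significant
  g_sig <- cached("gamm_cgm1", fit_gamm(sim_cortical(1)$data, "cortical_gm"))
  expect_gt(classify_shape(g_sig, "age")$edf, 2)
  sig <- smooth_significance(g_sig, "age")
  expect_lt(sig[["p"]], 0.001)
  expect_gt(sig[["F"]], 50)
  # edf stays within its bound k - 1 and residuals centre on zero
  expect_lte(g_sig$smooth_table["s(age)", "edf"], 6 + 1e-6)
  expect_lt(abs(mean(g_sig$residuals)), 1e-6 * sd(sim_cortical(1)$data$volume))
})

test_that("a zero-sex-effect generator leaves the difference smooth quiet", {
  g <- cached("gamm_cgm2", fit_gamm(sim_cortical(2)$data, "cortical_gm"))
  s2 <- smooth_significance(g, "age:sex")
  expect_lt(s2[["edf"]], 3)
  expect_gt(s2[["p"]], 0.01)
})

test_that("sex-shifted generation separates the stratified trajectories", {
  m <- preset("cortical_gm")
  m$sex_effects["inflection"] <- 4.92
  sim <- cached("cgm_sexshift",
                simulate_cohort(design_config(seed = 6), m, "cortical_gm"))
  sf <- stratified_fits(sim$data, "cortical_gm")
  grid <- data.frame(age = seq(10, 20, by = 0.25))
  pf <- sapply(sf, function(f) {
    newd <- data.frame(age = grid$age, subject = f$data$subject[1])
    braintraj:::population_prediction(f, newd)
  })
  # steepest decline later in males than females
  steep <- apply(pf, 2, function(v) grid$age[which.min(diff(v))])
  expect_gt(steep[["male"]], steep[["female"]])

  # stratified fit on single-sex input equals the whole-sample fit on it
  fem <- sim$data[sim$data$sex == "female", ]
  solo <- fit_gamm(long_volumes(fem), "cortical_gm",
                   smooth_spec(sex_smooth = FALSE))
  expect_equal(solo$smooth_table["s(age)", "edf"],
               sf$female$smooth_table["s(age)", "edf"], tolerance = 1e-6)
})

test_that("random-slope sensitivity changes edf by less than one", {
  d <- sim_cortical(1)$data
  g1 <- cached("gamm_cgm1", fit_gamm(d, "cortical_gm"))
  g2 <- fit_gamm(d, "cortical_gm", smooth_spec(random = "intercept+slope"))
  expect_lt(abs(g1$smooth_table["s(age)", "edf"] -
                  g2$smooth_table["s(age)", "edf"]), 1)
})
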