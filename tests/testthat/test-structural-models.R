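test_that("logistic evaluation matches hand-computed values", {
  # published cortical grey matter group parameters (rescaled units)
  p <- c(a_lower = 5089.72, a_upper = 6105.41, inflection = 14.52, hill = -5.94)
  # at x = inflection the power term is 1: asymptote midpoint
  expect_equal(eval_logistic(14.52, p[1], p[2], p[3], p[4]),
               (5089.72 + 6105.41) / 2)
  # scalar hand evaluation of the formula at x = 7:
  # 5089.72 + 1015.69 / (1 + (7/14.52)^5.94) = 6092.26...
  expect_equal(eval_logistic(7, p[1], p[2], p[3], p[4]), 6092.3,
               tolerance = 0.1 / 6092.3)
  # upper-asymptote limit for positive hill
  expect_equal(eval_logistic(1e6, 0, 1, 10, 4), 1, tolerance = 1e-6)
  expect_error(eval_logistic(-1, 0, 1, 10, 4), "> 0")
})

test_that("logistic identities hold across random parameter draws", {
  set.seed(11)
  for (i in 1:200) {
    aL <- runif(1, -100, 6000); aU <- runif(1, -100, 6000)
    infl <- runif(1, 0.5, 25); hill <- runif(1, -10, 10)
    # midpoint identity
    expect_equal(eval_logistic(infl, aL, aU, infl, hill), (aL + aU) / 2)
    # asymptote-swap + hill-negation symmetry
    x <- runif(5, 1, 25)
    expect_equal(eval_logistic(x, aL, aU, infl, hill),
                 eval_logistic(x, aU, aL, infl, -hill))
  }
  # monotone in x with direction sign(hill * (aU - aL))
  x <- seq(1, 25, length.out = 100)
  y_up <- eval_logistic(x, 100, 200, 12, 5)
  y_dn <- eval_logistic(x, 5089.72, 6105.41, 14.52, -5.94)
  expect_true(all(diff(y_up) > 0))
  expect_true(all(diff(y_dn) < 0))
})

test_that("logarithmic and linear functions are evaluated exactly", {
  expect_equal(eval_logarithmic(3.7, 5, 0), 5)
  expect_equal(eval_logarithmic(1, 0, 1), 0)
  expect_equal(eval_logarithmic(exp(1), 2, 3), 5)
  expect_error(eval_logarithmic(0, 1, 1), "> 0")
  # caudate published intercept/slope at age 10
  expect_equal(eval_linear(10, 4673.60, -31.00), 4363.60)
  expect_equal(eval_linear(3, 1, 2), 7)
  expect_equal(eval_linear(5, 0, 0), 0)
})

test_that("individual parameter assembly applies covariates and random effects", {
  pop <- c(a_lower = 5089.72, a_upper = 6105.41, inflection = 14.52, hill = -5.94)
  cm <- covariate_map(c("inflection", "hill"), c("sex", "euler"))
  coefs <- c(sex.inflection = 4.92, euler.hill = 0.01)

  # reference female, zero motion, zero random effect: unchanged
  phi_f <- individual_params(pop, c(sex = 0, euler = 0), cm, coefs)
  expect_equal(phi_f, pop)
  # male shift on the inflection (published sex coefficient)
  phi_m <- individual_params(pop, c(sex = 1, euler = 0), cm, coefs)
  expect_equal(phi_m[["inflection"]], 19.44)
  # euler -200 with 0.01 on the hill shifts it by -2
  phi_e <- individual_params(pop, c(sex = 0, euler = -200), cm, coefs)
  expect_equal(phi_e[["hill"]], -5.94 - 2)
  # random effects add on top
  phi_r <- individual_params(pop, c(sex = 0, euler = 0), cm, coefs,
                             random_effect = c(inflection = 1.5))
  expect_equal(phi_r[["inflection"]], 16.02)
  expect_error(individual_params(pop, c(sex = 1), cm, coefs), "euler")
})

test_that("covariate maps respect uniqueness and per-function ceilings", {
  expect_error(covariate_map(c("hill", "hill"), c("sex", "sex")), "at most once")
  big <- covariate_map(rep(c("a", "b"), each = 3),
                       rep(c("sex", "euler", "software"), 2))
  expect_error(braintraj:::validate_covariate_map(big, "linear"), "at most 4")
  big_logistic <- covariate_map(rep(c("a_lower", "hill"), each = 3),
                                rep(c("sex", "euler", "software"), 2))
  expect_silent(braintraj:::validate_covariate_map(big_logistic, "logistic"))
  expect_error(braintraj:::validate_covariate_map(
    covariate_map("inflection", "sex"), "linear"), "unknown parameter")
})
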