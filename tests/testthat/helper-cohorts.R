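# Shared fixtures: cohorts are simulated in code and expensive fits cached
# per test run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) {
    assign(key, force(expr), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# fast but adequate estimation settings for test-sized checks
test_control <- function(compute_se = FALSE) {
  nlmm_control(saem_burnin = 200, saem_smooth = 120, polish_maxit = 200,
               is_samples = 400, compute_se = compute_se)
}

sim_cortical <- function(seed = 1, effects = "none") {
  cached(paste0("cgm", seed, effects),
         simulate_cohort(design_config(seed = seed),
                         preset("cortical_gm", effects = effects),
                         "cortical_gm"))
}

sim_caudate <- function(seed = 1) {
  cached(paste0("cau", seed),
         simulate_cohort(design_config(seed = seed), preset("caudate"), "caudate"))
}

# one shared logistic fit on the cortical preset (used by several files)
fit_cortical <- function(seed = 1) {
  cached(paste0("fit_cgm", seed), {
    sim <- sim_cortical(seed)
    fit_nlmm(sim$data, "cortical_gm", structural_spec("logistic"),
             seed = 500 + seed, control = test_control(compute_se = TRUE))
  })
}

# small three-subject linear toy dataset with exact structure
toy_linear_data <- function(n_subj = 12, resid_sd = 1, seed = 42,
                            a = 100, b = -3, sd_a = 5, sd_b = 0.5) {
  set.seed(seed)
  rows <- lapply(seq_len(n_subj), function(i) {
    ai <- a + rnorm(1, 0, sd_a); bi <- b + rnorm(1, 0, sd_b)
    x <- seq(8, 20, by = 1.5)
    data.frame(subject_id = sprintf("T%02d", i), wave = seq_along(x),
               age = x, sex = if (i %% 2) "female" else "male",
               region = "caudate", volume = ai + bi * x + rnorm(length(x), 0, resid_sd),
               euler = -100, software = "sw1", stringsAsFactors = FALSE)
  })
  long_volumes(do.call(rbind, rows))
}
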