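#' Accelerated longitudinal design configuration
#'
#' Describes a multi-wave accelerated longitudinal study: subjects enter at
#' staggered baseline ages drawn uniformly from \code{baseline_age_range} and
#' are revisited at the fixed \code{wave_offsets}. The default emulates a
#' 12-wave design with 90 subjects, baselines between 7.60 and 12.90 years,
#' six-month intervals for the first ten waves, one year to wave 11 and three
#' years to wave 12, so the study spans roughly ages 7.6 to 21.6. Each
#' non-baseline visit is independently missing with probability
#' \code{visit_missing_prob} (default 0.31, giving about 8.6 retained scans
#' per subject on average); the baseline visit is never dropped, so every
#' simulated subject exists in the data. Visit timing receives small Gaussian
#' jitter (SD \code{timing_jitter_sd} years) since real visits are not
#' exactly on schedule.
#'
#' @param n_subjects number of subjects (default 90).
#' @param baseline_age_range length-2 numeric, years.
#' @param wave_offsets strictly increasing offsets in years, starting at 0.
#' @param visit_missing_prob probability in [0, 1) that a non-baseline visit
#'   is missing.
#' @param timing_jitter_sd SD (years) of visit-timing jitter.
#' @param female_fraction expected fraction of female subjects (default
#'   53/90).
#' @param seed integer RNG seed making the whole simulation reproducible.
#' @return A list of class \code{design_config}.
#' @export
design_config <- function(n_subjects = 90,
                          baseline_age_range = c(7.60, 12.90),
                          wave_offsets = c(0, 0.5, 1.0, 1.5, 2.0, 2.5,
                                           3.0, 3.5, 4.0, 4.5, 5.5, 8.5),
                          visit_missing_prob = 0.31,
                          timing_jitter_sd = 0.05,
                          female_fraction = 53 / 90,
                          seed = 1L) {
  stopifnot(n_subjects >= 1,
            length(baseline_age_range) == 2,
            diff(baseline_age_range) >= 0,
            wave_offsets[1] == 0,
            all(diff(wave_offsets) > 0),
            visit_missing_prob >= 0, visit_missing_prob < 1,
            timing_jitter_sd >= 0,
            female_fraction >= 0, female_fraction <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 baseline_age_range = baseline_age_range,
                 wave_offsets = wave_offsets,
                 visit_missing_prob = visit_missing_prob,
                 timing_jitter_sd = timing_jitter_sd,
                 female_fraction = female_fraction,
                 seed = as.integer(seed)),
            class = "design_config")
}

# Scanner software epochs: five ordinal versions assigned by calendar
# position of the wave across the study span (all subjects share calendar
# time in a single-cohort design, so the epoch is a function of the wave
# offset).
software_epoch <- function(offsets, total_span) {
  idx <- pmin(5L, 1L + floor(5 * offsets / (total_span + 1e-9)))
  paste0("sw", idx)
}

# Draw mean Euler numbers: Normal(-150, 80) truncated above at 0 (more
# negative = more in-scanner motion), via the inverse-CDF method so one
# uniform draw is consumed per visit.
draw_euler <- function(n, mean = -150, sd = 80) {
  u <- stats::runif(n, 0, stats::pnorm(0, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Sample a per-subject visit schedule
#'
#' Realizes the design: baseline ages, sexes, retained visits, jittered visit
#' ages, per-visit Euler numbers and scanner-software epochs. Fully
#' deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{design_config}}.
#' @return A data.frame with one row per retained visit: \code{subject_id},
#'   \code{sex}, \code{wave}, \code{age}, \code{euler}, \code{software}.
#' @export
sample_design <- function(config) {
  stopifnot(inherits(config, "design_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  offs <- config$wave_offsets
  nw <- length(offs)
  span <- max(offs)

  baseline <- stats::runif(n, config$baseline_age_range[1], config$baseline_age_range[2])
  n_female <- round(config$female_fraction * n)
  sex <- sample(rep(c("female", "male"), c(n_female, n - n_female)))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      ages <- baseline[i] + offs + stats::rnorm(nw, 0, config$timing_jitter_sd)
      if (all(diff(ages) > 0)) break  # redraw in the rare event jitter reorders visits
    }
    keep <- c(TRUE, stats::runif(nw - 1) >= config$visit_missing_prob)
    rows[[i]] <- data.frame(
      subject_id = sprintf("S%03d", i),
      sex = sex[i],
      wave = seq_len(nw)[keep],
      age = ages[keep],
      euler = draw_euler(sum(keep)),
      software = software_epoch(offs[keep], span),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Generative growth model for cohort simulation
#'
#' Specifies the ground truth from which volumes are simulated: a structural
#' function, its population parameters, additive male shifts per parameter
#' (female reference), a motion coefficient on the slope-like parameter
#' (hill for the logistic, b otherwise) applied to the subject-mean Euler
#' number, diagonal between-subject Gaussian SDs on the natural parameter
#' scale, and an additive residual SD.
#'
#' @param fun one of \code{"logistic"}, \code{"logarithmic"}, \code{"linear"}.
#' @param params named numeric population parameter vector.
#' @param sex_effects named numeric additive shifts for males (defaults to
#'   zero for all parameters).
#' @param motion_effect coefficient of subject-mean euler on the slope-like
#'   parameter (default 0).
#' @param between_sd named nonnegative SDs of the per-parameter random
#'   effects.
#' @param residual_sd positive additive residual SD (volume units).
#' @param rescaled TRUE if \code{params} are on the divided-by-100 scale used
#'   for the global measures.
#' @return A list of class \code{generative_model}.
#' @export
generative_model <- function(fun, params, sex_effects = NULL, motion_effect = 0,
                             between_sd = NULL, residual_sd, rescaled = FALSE) {
  pn <- structural_params(fun)
  stopifnot(setequal(names(params), pn), residual_sd > 0)
  params <- params[pn]
  zero <- setNames(numeric(length(pn)), pn)
  sex_effects <- if (is.null(sex_effects)) zero else {
    out <- zero; out[names(sex_effects)] <- sex_effects; out
  }
  between_sd <- if (is.null(between_sd)) zero else {
    out <- zero; out[names(between_sd)] <- between_sd; out
  }
  stopifnot(all(between_sd >= 0))
  structure(list(fun = fun, params = params, sex_effects = sex_effects,
                 motion_effect = motion_effect, between_sd = between_sd,
                 residual_sd = residual_sd, rescaled = rescaled),
            class = "generative_model")
}

# Printed group-level estimates used as generating truth. Global measures
# (cortical_gm, white_matter) are on the divided-by-100 scale on which they
# were estimated. Sex effects are additive male shifts; motion coefficients
# act on the hill (logistic) or b (logarithmic). Linear regions carry sex
# effects on intercept and slope only.
PRESETS <- list(
  cortical_gm = list(fun = "logistic", rescaled = TRUE,
    params = c(a_lower = 5089.72, a_upper = 6105.41, inflection = 14.52, hill = -5.94),
    sex = c(a_lower = -232.79, a_upper = 488.24, inflection = 4.92, hill = 2.10),
    motion = 0.01),
  white_matter = list(fun = "logistic", rescaled = TRUE,
    params = c(a_lower = 3736.34, a_upper = 4555.92, inflection = 13.91, hill = 3.89),
    sex = c(a_lower = 289.28, a_upper = 544.69, inflection = -1.64, hill = 0.17),
    motion = 0.003),
  pallidum = list(fun = "logistic", rescaled = FALSE,
    params = c(a_lower = 1741.55, a_upper = 2154.30, inflection = 10.99, hill = 5.17),
    sex = c(a_lower = 192.86, a_upper = 230.59, inflection = 1.61, hill = 1.74),
    motion = 0.0016),
  accumbens = list(fun = "logistic", rescaled = FALSE,
    params = c(a_lower = 435.33, a_upper = 674.27, inflection = 11.44, hill = -0.43),
    sex = c(a_lower = 133.73, a_upper = 44.17, inflection = -2.90, hill = -0.81),
    motion = 0.01),
  hippocampus = list(fun = "linear", rescaled = FALSE,
    params = c(a = 4116.00, b = 6.50), sex = c(a = 58.60, b = 13.40), motion = 0),
  amygdala = list(fun = "linear", rescaled = FALSE,
    params = c(a = 1639.66, b = 6.44), sex = c(a = 115.55, b = 5.32), motion = 0),
  caudate = list(fun = "linear", rescaled = FALSE,
    params = c(a = 4673.60, b = -31.00), sex = c(a = 45.90, b = 14.40), motion = 0),
  putamen = list(fun = "linear", rescaled = FALSE,
    params = c(a = 6185.50, b = -45.70), sex = c(a = 317.50, b = 16.30), motion = 0),
  thalamus = list(fun = "linear", rescaled = FALSE,
    params = c(a = 8095.50, b = -24.40), sex = c(a = 530.70, b = 17.10), motion = 0)
)

#' Region presets for cohort simulation
#'
#' Returns a \code{\link{generative_model}} whose population parameters are
#' the published group-level estimates for the named region. Defaults for
#' the unpublished variance components follow a stated convention:
#' between-subject SD of each parameter is 5\% of its absolute value, and the
#' residual SD is 2\% of the asymptote midpoint (logistic) or of the fitted
#' value at the design mid-age of 14.6 years (logarithmic/linear).
#'
#' With \code{effects = "none"} (the default) the generating model carries no
#' sex or motion effects, so the population parameters are the unconditional
#' truth for every subject; \code{effects = "paper"} switches on the
#' published sex shifts and motion coefficient.
#'
#' @param name region name; one of the logistic regions
#'   (\code{cortical_gm}, \code{white_matter}, \code{pallidum},
#'   \code{accumbens}) or the linear regions (\code{hippocampus},
#'   \code{amygdala}, \code{caudate}, \code{putamen}, \code{thalamus}).
#' @param effects \code{"none"} or \code{"paper"}.
#' @return A \code{generative_model}.
#' @examples
#' preset("cortical_gm")$params[["inflection"]]  # 14.52
#' @export
preset <- function(name, effects = c("none", "paper")) {
  effects <- match.arg(effects)
  if (!name %in% names(PRESETS)) {
    stop("unknown preset '", name, "'; valid names: ",
         paste(names(PRESETS), collapse = ", "), call. = FALSE)
  }
  p <- PRESETS[[name]]
  mid <- if (p$fun == "logistic") {
    (p$params[["a_lower"]] + p$params[["a_upper"]]) / 2
  } else {
    abs(eval_structural(p$fun, 14.6, as.list(p$params)))
  }
  generative_model(
    fun = p$fun,
    params = p$params,
    sex_effects = if (effects == "paper") p$sex else NULL,
    motion_effect = if (effects == "paper") p$motion else 0,
    between_sd = abs(p$params) * 0.05,
    residual_sd = 0.02 * mid,
    rescaled = p$rescaled
  )
}

#' Simulate an accelerated longitudinal cohort with known truth
#'
#' Draws a visit schedule from the design, realizes per-subject growth
#' parameters \eqn{\phi_i = \beta + \delta_{sex}\,male_i + \gamma\,\bar e_i +
#' \eta_i} with \eqn{\eta_i \sim N(0, \mathrm{diag}(\sigma^2))} (the motion
#' term \eqn{\gamma \bar e_i} uses the subject-mean Euler number and acts on
#' the slope-like parameter), and generates volumes
#' \eqn{y_{ij} = f(age_{ij}; \phi_i) + \epsilon_{ij}}. Subjects whose drawn
#' logistic inflection is not positive are resampled (counted and warned
#' about) so the growth function stays defined. Fully reproducible under the
#' design seed.
#'
#' @param design a \code{\link{design_config}}.
#' @param model a \code{\link{generative_model}} or \code{\link{preset}}.
#' @param region region label for the generated records.
#' @return A list with \code{data} (a \code{\link{long_volumes}} dataset) and
#'   \code{truth} (a list with per-subject realized parameters and random
#'   effects, and the per-visit schedule).
#' @export
simulate_cohort <- function(design, model, region) {
  stopifnot(inherits(design, "design_config"), inherits(model, "generative_model"))
  visits <- sample_design(design)   # seeds the RNG from design$seed
  pn <- names(model$params)
  subjects <- unique(visits[c("subject_id", "sex")])
  ns <- nrow(subjects)
  mean_euler <- tapply(visits$euler, visits$subject_id, mean)[subjects$subject_id]

  slope_par <- if (model$fun == "logistic") "hill" else "b"
  n_resampled <- 0L
  phi <- matrix(NA_real_, ns, length(pn), dimnames = list(subjects$subject_id, pn))
  eta <- phi
  for (i in seq_len(ns)) {
    base <- model$params +
      model$sex_effects * (subjects$sex[i] == "male")
    base[slope_par] <- base[slope_par] + model$motion_effect * mean_euler[i]
    repeat {
      e <- stats::rnorm(length(pn), 0, model$between_sd)
      cand <- base + e
      ok <- !(model$fun == "logistic" && cand[["inflection"]] <= 0)
      if (ok) break
      n_resampled <- n_resampled + 1L
    }
    phi[i, ] <- cand
    eta[i, ] <- e
  }
  if (n_resampled > 0) {
    warning(n_resampled, " degenerate parameter draw(s) (inflection <= 0) resampled")
  }

  idx <- match(visits$subject_id, subjects$subject_id)
  mu <- vapply(seq_len(nrow(visits)), function(j) {
    eval_structural(model$fun, visits$age[j], as.list(phi[idx[j], ]))
  }, numeric(1))
  volume <- mu + stats::rnorm(nrow(visits), 0, model$residual_sd)

  df <- data.frame(subject_id = visits$subject_id, wave = visits$wave,
                   age = visits$age, sex = visits$sex, region = region,
                   volume = volume, euler = visits$euler,
                   software = visits$software, stringsAsFactors = FALSE)
  data <- long_volumes(df, study = "synthetic")
  if (isTRUE(model$rescaled)) {
    rs <- attr(data, "rescale")
    rs[region] <- 100
    attr(data, "rescale") <- rs
  }
  truth_subjects <- data.frame(subjects, mean_euler = as.numeric(mean_euler),
                               phi, check.names = FALSE)
  truth_ranef <- data.frame(subject_id = subjects$subject_id, eta, check.names = FALSE)
  list(data = data,
       truth = list(model = model, subjects = truth_subjects,
                    random_effects = truth_ranef, visits = visits,
                    n_resampled = n_resampled))
}
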