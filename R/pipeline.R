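# Per-region analysis orchestration: GAMM shape call, candidate NLMMs,
# criterion-based family selection, forward-stepwise covariate selection,
# individual-differences summaries, baseline-change correlations, and the
# sensitivity arms.

#' Select the best-fitting structural function
#'
#' Given converged candidate fits of different structural functions on the
#' same data and response scale, selects the function minimizing BIC. When
#' AIC and BIC disagree, BIC wins and the disagreement is recorded (BIC's
#' stronger complexity penalty suits selecting among function families).
#'
#' @param fits named list of \code{population_fit}s (names = function names).
#' @return A list with \code{selected}, the criteria table, and
#'   \code{aic_bic_disagree}.
#' @export
select_structural_model <- function(fits) {
  conv <- vapply(fits, function(f) isTRUE(f$convergence$converged), logical(1))
  if (!any(conv)) stop("no converged candidate fits", call. = FALSE)
  fits <- fits[conv]
  crit <- data.frame(
    fun = vapply(fits, `[[`, character(1), "fun"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    row.names = NULL
  )
  by_bic <- crit$fun[which.min(crit$bic)]
  by_aic <- crit$fun[which.min(crit$aic)]
  list(selected = by_bic, criteria = crit,
       aic_bic_disagree = by_aic != by_bic,
       aic_choice = by_aic)
}

#' Forward-stepwise covariate selection
#'
#' Greedy forward selection over candidate covariate-to-parameter entries:
#' at each round every single remaining entry is added to the current map,
#' the model refitted, and the entry giving the largest BIC improvement is
#' accepted; selection stops when no addition improves BIC. Accepted steps
#' therefore strictly decrease the criterion. Deterministic under
#' \code{seed}.
#'
#' @param data a \code{\link{long_volumes}} dataset.
#' @param region region to fit.
#' @param fun structural function name.
#' @param candidates a \code{\link{covariate_map}} of candidate entries
#'   (respecting the per-function ceiling).
#' @param seed integer seed (each refit uses a seed derived from it).
#' @param control a \code{\link{nlmm_control}}.
#' @return A list of class \code{stepwise_trace}: \code{steps} (one row per
#'   evaluated round: entry, bic before/after, accepted), \code{final_map},
#'   and the final \code{fit}.
#' @export
stepwise_covariates <- function(data, region, fun, candidates, seed = 1L,
                                control = nlmm_control()) {
  validate_covariate_map(candidates, fun)
  current <- covariate_map()
  base_fit <- fit_nlmm(data, region, structural_spec(fun, covariates = current),
                       seed = seed, control = control)
  bic_cur <- base_fit$bic
  steps <- list()
  remaining <- candidates
  round_i <- 0L
  fit_cur <- base_fit
  while (nrow(remaining) > 0) {
    round_i <- round_i + 1L
    bics <- rep(NA_real_, nrow(remaining))
    fits <- vector("list", nrow(remaining))
    for (j in seq_len(nrow(remaining))) {
      cand_map <- covariate_map(c(current$parameter, remaining$parameter[j]),
                                c(current$covariate, remaining$covariate[j]))
      f <- try(fit_nlmm(data, region,
                        structural_spec(fun, covariates = cand_map),
                        seed = seed + 1000L * round_i + j, control = control),
               silent = TRUE)
      if (!inherits(f, "try-error") && isTRUE(f$convergence$converged)) {
        bics[j] <- f$bic
        fits[[j]] <- f
      }
    }
    if (all(is.na(bics))) break
    jbest <- which.min(bics)
    accepted <- bics[jbest] < bic_cur
    steps[[length(steps) + 1]] <- data.frame(
      round = round_i,
      parameter = remaining$parameter[jbest],
      covariate = remaining$covariate[jbest],
      bic_before = bic_cur, bic_after = bics[jbest],
      accepted = accepted
    )
    if (!accepted) break
    current <- covariate_map(c(current$parameter, remaining$parameter[jbest]),
                             c(current$covariate, remaining$covariate[jbest]))
    fit_cur <- fits[[jbest]]
    bic_cur <- bics[jbest]
    remaining <- remaining[-jbest, , drop = FALSE]
  }
  structure(list(steps = do.call(rbind, steps) %||%
                   data.frame(round = integer(), parameter = character(),
                              covariate = character(), bic_before = numeric(),
                              bic_after = numeric(), accepted = logical()),
                 final_map = current, fit = fit_cur),
            class = "stepwise_trace")
}

#' Summarize individual differences in the derived growth scalar
#'
#' Minimum, maximum, range, mean, density-ready quantiles and (optionally)
#' per-sex means of the per-subject derived scalar (inflection point or rate
#' parameter).
#'
#' @param individual an \code{\link{individual_estimates}} result.
#' @param by_sex logical; add per-sex means.
#' @return A list of summary statistics.
#' @export
summarize_individual_differences <- function(individual, by_sex = TRUE) {
  v <- individual$derived
  out <- list(scalar = attr(individual, "scalar"),
              n = length(v), min = min(v), max = max(v),
              range = max(v) - min(v), mean = mean(v), sd = stats::sd(v),
              quantiles = stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  if (by_sex) {
    out$mean_by_sex <- tapply(v, individual$sex, mean)
    if (all(c("female", "male") %in% names(out$mean_by_sex))) {
      out$male_minus_female <- unname(out$mean_by_sex["male"] -
                                        out$mean_by_sex["female"])
    }
  }
  out
}

#' Correlate baseline level with magnitude of change
#'
#' Pearson correlation between the individual estimates of a baseline
#' parameter (an asymptote or intercept) and the \emph{absolute} individual
#' estimates of a change parameter (hill or slope — absolute values reflect
#' the magnitude of change irrespective of direction), with df = n - 2.
#'
#' @param individual an \code{\link{individual_estimates}} result.
#' @param baseline_param,change_param structural parameter names.
#' @return A list with \code{r}, \code{df}, \code{p} (and the inputs used).
#' @export
correlate_baseline_change <- function(individual, baseline_param, change_param) {
  stopifnot(nrow(individual) >= 3)
  xb <- individual[[baseline_param]]
  xc <- abs(individual[[change_param]])
  if (stats::sd(xb) == 0 || stats::sd(xc) == 0) {
    return(list(r = NA_real_, df = nrow(individual) - 2L, p = NA_real_,
                note = "zero variance in one of the vectors"))
  }
  ct <- stats::cor.test(xb, xc, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value,
       baseline_param = baseline_param, change_param = change_param)
}

# The covariate structure used for reported covariate models: sex on every
# structural parameter, plus motion (euler) on the slope-like parameter for
# the logistic and logarithmic functions.
standard_covariate_map <- function(fun) {
  pn <- structural_params(fun)
  cm <- covariate_map(pn, rep("sex", length(pn)))
  if (fun == "logistic") {
    cm <- covariate_map(c(pn, "hill"), c(rep("sex", length(pn)), "euler"))
  } else if (fun == "logarithmic") {
    cm <- covariate_map(c(pn, "b"), c(rep("sex", length(pn)), "euler"))
  }
  cm
}

#' Run the full per-region analysis
#'
#' Orchestrates one region end to end: adjustment GAMM and shape call, the
#' three candidate NLMMs (all fitted regardless of the shape call, with the
#' conditional logic recorded), BIC selection, the covariate model (the
#' standard covariate structure, or a stepwise-selected one), individual
#' estimates, individual-differences summary, out-of-range flags and CV
#' gates.
#'
#' @param data a \code{\link{long_volumes}} dataset (QC assumed already
#'   applied, or waived deliberately).
#' @param region region to analyse.
#' @param seed integer seed.
#' @param covariates \code{"standard"} (transfer the standard structure),
#'   \code{"none"}, or a \code{\link{covariate_map}}.
#' @param gamm_spec a \code{\link{smooth_spec}} for the shape stage.
#' @param control a \code{\link{nlmm_control}}.
#' @return A list of class \code{region_report}.
#' @export
run_region_analysis <- function(data, region, seed = 1L,
                                covariates = "standard",
                                gamm_spec = smooth_spec(),
                                control = nlmm_control()) {
  if (!any(data$region == region)) {
    stop("ingestion: no observations for region '", region, "'", call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  gamm <- stage("gamm", fit_gamm(data, region, gamm_spec))
  shape <- classify_shape(gamm, "age")

  funs <- c("logistic", "logarithmic", "linear")
  cand <- stage("candidate-nlmms", {
    fits <- list()
    for (fn in funs) {
      f <- try(fit_nlmm(data, region,
                        structural_spec(fn, covariates = covariate_map()),
                        seed = seed, control = control), silent = TRUE)
      if (!inherits(f, "try-error")) fits[[fn]] <- f
    }
    if (!length(fits)) stop("no candidate fit converged")
    fits
  })
  sel <- stage("selection", select_structural_model(cand))

  cm <- if (identical(covariates, "standard")) standard_covariate_map(sel$selected)
        else if (identical(covariates, "none")) covariate_map()
        else covariates
  covfit <- stage("covariate-model",
                  fit_nlmm(data, region,
                           structural_spec(sel$selected, covariates = cm),
                           seed = seed + 7L, control = control))
  ind <- stage("individual-estimates", individual_estimates(covfit, data))
  summ <- summarize_individual_differences(ind)
  age_range <- range(data$age[data$region == region])
  flags <- if (covfit$fun == "logistic") flag_out_of_range(ind, age_range)
           else flag_out_of_range(ind, c(-Inf, Inf))[0, ]

  structure(list(
    region = region,
    gamm = list(smooth_table = gamm$smooth_table,
                parametric_table = gamm$parametric_table),
    shape = shape,
    nlmm_conditional_on_shape = shape$classification != "linear",
    criteria = sel$criteria, selected = sel$selected,
    aic_bic_disagree = sel$aic_bic_disagree,
    fit = covfit,
    cv_gate = cv_gate(covfit$estimates, covfit$standard_errors),
    individual = ind, individual_summary = summ,
    out_of_range = flags,
    age_range = age_range,
    seed = seed
  ), class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat("<region_report> ", x$region, "\n", sep = "")
  cat("  GAMM shape: ", x$shape$classification,
      " (edf ", round(x$shape$edf, 2), ")",
      if (!x$nlmm_conditional_on_shape)
        " [NLMM stage run despite linear shape call]", "\n", sep = "")
  cat("  selected function: ", x$selected,
      if (x$aic_bic_disagree) " (AIC disagreed; BIC used)", "\n", sep = "")
  print(x$criteria)
  cat("  ", x$individual_summary$scalar, ": mean ",
      round(x$individual_summary$mean, 3), ", range ",
      round(x$individual_summary$min, 2), "-",
      round(x$individual_summary$max, 2), "\n", sep = "")
  if (nrow(x$out_of_range)) {
    cat("  ", nrow(x$out_of_range), " out-of-range timing estimate(s)\n", sep = "")
  }
  invisible(x)
}

#' Sensitivity analyses around a main NLMM/GAMM result
#'
#' Three refit arms: (a) the selected NLMM with an empty covariate map;
#' (b) the GAMM with an eTIV main effect added; (c) the GAMM with a
#' scanner-software main effect added and the NLMM with software as a
#' covariate on the parameter of interest (inflection or b). Each arm
#' reports deltas against the main model; arms whose covariate column is
#' absent are skipped with a notice.
#'
#' @param data a \code{\link{long_volumes}} dataset.
#' @param region region to analyse.
#' @param main_fit the main \code{population_fit} (with covariates).
#' @param seed integer seed.
#' @param control a \code{\link{nlmm_control}}.
#' @return A list with one entry per arm (\code{no_covariates}, \code{etiv},
#'   \code{software}), each carrying the refit summary and parameter deltas,
#'   or a skip notice.
#' @export
sensitivity_suite <- function(data, region, main_fit, seed = 1L,
                              control = nlmm_control()) {
  fun <- main_fit$fun
  pn <- structural_params(fun)
  scalar <- derived_scalar_name(fun)
  out <- list()

  f_a <- fit_nlmm(data, region, structural_spec(fun, covariates = covariate_map()),
                  seed = seed, control = control)
  out$no_covariates <- list(
    estimates = f_a$estimates,
    delta = f_a$estimates[pn] - main_fit$estimates[pn],
    fit = f_a
  )

  if ("etiv" %in% names(data) && !all(is.na(data$etiv))) {
    g_b <- fit_gamm(data, region, smooth_spec(covariates = "etiv"))
    out$etiv <- list(
      parametric_table = g_b$parametric_table,
      smooth_table = g_b$smooth_table,
      sex_estimate = if ("sexomale" %in% rownames(g_b$parametric_table))
        g_b$parametric_table["sexomale", ] else NULL
    )
  } else {
    out$etiv <- list(skipped = "no etiv column in dataset")
  }

  if ("software" %in% names(data)) {
    g_c <- fit_gamm(data, region, smooth_spec(covariates = "software"))
    cm_c <- covariate_map(
      c(main_fit$spec$covariates$parameter, scalar),
      c(main_fit$spec$covariates$covariate, "software")
    )
    f_c <- fit_nlmm(data, region, structural_spec(fun, covariates = cm_c),
                    seed = seed + 13L, control = control)
    key <- paste("software", scalar, sep = ".")
    out$software <- list(
      gamm_smooth_table = g_c$smooth_table,
      software_coef = f_c$estimates[[key]],
      software_p = f_c$wald_p[[key]],
      scalar_main = main_fit$estimates[[scalar]],
      scalar_adjusted = f_c$estimates[[scalar]],
      scalar_delta = f_c$estimates[[scalar]] - main_fit$estimates[[scalar]]
    )
  } else {
    out$software <- list(skipped = "no software column in dataset")
  }
  out
}
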