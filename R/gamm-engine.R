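# Penalized-spline mixed models (GAMMs) for data-driven trajectory shape.
# Estimation is delegated to mgcv::gam with REML smoothing selection; this
# module fixes the model construction the analyses rely on: a k=7 thin-plate
# age smooth for the reference sex (female), an ordered-factor difference
# smooth for the male deviation, a sex intercept contrast, and a subject
# random intercept (optionally random slope) as penalized "re" terms.

#' Smooth model specification
#'
#' @param k basis dimension of the age smooths (default 7; must be >= 3).
#' @param covariates parametric main effects besides sex: any of
#'   \code{"etiv"}, \code{"software"}.
#' @param random \code{"intercept"} (default) or \code{"intercept+slope"} —
#'   per-subject random terms estimated jointly with the smoothing
#'   parameters by REML.
#' @param sex_smooth logical; include the ordered-factor male difference
#'   smooth (age-by-sex interaction).
#' @return An object of class \code{smooth_spec}.
#' @export
smooth_spec <- function(k = 7, covariates = character(),
                        random = c("intercept", "intercept+slope"),
                        sex_smooth = TRUE) {
  random <- match.arg(random)
  stopifnot(k >= 3, all(covariates %in% c("etiv", "software")))
  structure(list(k = k, covariates = covariates, random = random,
                 sex_smooth = sex_smooth),
            class = "smooth_spec")
}

#' Thin-plate spline basis and penalty for an age smooth
#'
#' Exposes the low-rank thin-plate regression spline construction used by
#' the trajectory smooths: \code{k} basis columns and the positive
#' semidefinite wiggliness penalty whose null space contains constant and
#' linear functions of age (so straight lines are penalty-free).
#'
#' @param ages numeric vector of ages with at least \code{k} distinct values.
#' @param k basis dimension.
#' @return A list with \code{X} (n x k design block) and \code{S} (k x k
#'   penalty matrix).
#' @export
build_basis <- function(ages, k = 7) {
  if (length(unique(ages)) < k) {
    stop("need at least k = ", k, " distinct ages (got ",
         length(unique(ages)), "); reduce k", call. = FALSE)
  }
  sc <- mgcv::smoothCon(mgcv::s(age, bs = "tp", k = k),
                        data = data.frame(age = ages))[[1]]
  list(X = sc$X, S = sc$S[[1]], null_space_dim = sc$null.space.dim)
}

# sex as an ordered factor with treatment contrasts: the parametric
# coefficient is the male - female intercept contrast and mgcv builds a
# centred male-only difference smooth for the by= term.
ordered_sex <- function(sex) {
  o <- factor(sex, levels = c("female", "male"), ordered = TRUE)
  stats::contrasts(o) <- stats::contr.treatment(2)
  o
}

#' Fit a penalized-smooth mixed model of volume against age
#'
#' Fits \eqn{y = \beta_0 + \beta_1 sex + s_1(age) + s_2(age)\,sex + u + \epsilon}
#' by REML: \eqn{s_1} is the reference (female) age smooth, \eqn{s_2} the
#' male difference smooth (ordered-factor construction, centred, own
#' smoothing parameter), \eqn{\beta_1} the male-female intercept contrast and
#' \eqn{u} a per-subject random intercept (plus random slope if requested)
#' estimated as a penalized ridge term jointly with the smoothing parameters.
#' Optional parametric main effects of eTIV and scanner-software version.
#'
#' The effective degrees of freedom (edf) of a smooth measure its
#' complexity: edf near 1 means the REML-selected fit is a straight line,
#' edf above 2 indicates clear nonlinearity (see
#' \code{\link{classify_shape}}).
#'
#' @param data a \code{\link{long_volumes}} dataset.
#' @param region region to fit.
#' @param spec a \code{\link{smooth_spec}}.
#' @return An object of class \code{smooth_fit}: the mgcv fit plus extracted
#'   parametric and smooth-term tables (edf, reference df, F, p — the
#'   reference df reported is mgcv's test df for the term), variance
#'   components, fitted values and residuals.
#' @export
fit_gamm <- function(data, region, spec = smooth_spec()) {
  stopifnot(inherits(data, "long_volumes"), inherits(spec, "smooth_spec"))
  df <- data[data$region == region, , drop = FALSE]
  if (!nrow(df)) stop("no observations for region '", region, "'", call. = FALSE)
  df <- as.data.frame(df)
  df$sexo <- ordered_sex(df$sex)
  df$subject <- factor(df$subject_id)
  if (length(unique(df$age)) < spec$k) {
    stop("fewer than k = ", spec$k, " distinct ages in region '", region, "'",
         call. = FALSE)
  }

  both_sexes <- length(unique(df$sex)) == 2
  terms <- c(if (both_sexes) "sexo", sprintf("s(age, k = %d)", spec$k))
  if (spec$sex_smooth && both_sexes) {
    terms <- c(terms, sprintf("s(age, by = sexo, k = %d)", spec$k))
  }
  if ("etiv" %in% spec$covariates) terms <- c(terms, "etiv")
  if ("software" %in% spec$covariates) {
    df$software <- factor(df$software)
    terms <- c(terms, "software")
  }
  terms <- c(terms, "s(subject, bs = \"re\")")
  if (spec$random == "intercept+slope") {
    terms <- c(terms, "s(age, subject, bs = \"re\")")
  }
  form <- stats::as.formula(paste("volume ~", paste(terms, collapse = " + ")))
  fit <- mgcv::gam(form, data = df, method = "REML")
  if (!fit$converged) warning("REML iteration did not converge for region ", region)

  sm <- summary(fit)
  s_tab <- as.data.frame(sm$s.table)
  names(s_tab) <- c("edf", "ref_df", "F", "p")
  p_tab <- as.data.frame(sm$p.table)
  names(p_tab) <- c("estimate", "se", "t", "p")
  vc <- tryCatch({
    tmp <- utils::capture.output(v <- mgcv::gam.vcomp(fit, rescale = FALSE))
    v
  }, error = function(e) NULL, warning = function(w) NULL)

  structure(list(gam = fit, region = region, spec = spec,
                 smooth_table = s_tab, parametric_table = p_tab,
                 vcomp = vc, converged = fit$converged,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit, type = "response"),
                 data = df),
            class = "smooth_fit")
}

#' @export
print.smooth_fit <- function(x, ...) {
  cat("<smooth_fit> region ", x$region, ", k = ", x$spec$k,
      ", random = ", x$spec$random, "\n", sep = "")
  cat("parametric terms:\n"); print(round(x$parametric_table, 4))
  cat("smooth terms:\n"); print(round(x$smooth_table, 4))
  invisible(x)
}

# resolve a user-facing term name to a smooth_table row
match_smooth_term <- function(fit, term) {
  rn <- rownames(fit$smooth_table)
  hit <- if (term %in% rn) term else {
    alias <- switch(term,
                    age = grep("^s\\(age\\)$", rn, value = TRUE),
                    "age:sex" = grep("^s\\(age\\):", rn, value = TRUE),
                    subject = grep("subject", rn, value = TRUE),
                    character(0))
    alias
  }
  if (length(hit) != 1) {
    stop("no unique smooth term matching '", term, "'; available: ",
         paste(rn, collapse = ", "), call. = FALSE)
  }
  hit
}

#' Classify trajectory shape from a smooth's edf
#'
#' edf within 0.1 of 1 is called \code{linear} (a REML fit never lands on 1.0
#' exactly), edf up to 2 \code{weakly nonlinear}, and edf above 2
#' \code{nonlinear}.
#'
#' @param fit a \code{smooth_fit}.
#' @param term smooth term; \code{"age"} (default) resolves to the reference
#'   age smooth.
#' @return A list with \code{edf} and \code{classification}.
#' @export
classify_shape <- function(fit, term = "age") {
  edf <- fit$smooth_table[match_smooth_term(fit, term), "edf"]
  cls <- if (abs(edf - 1) < 0.1) "linear"
         else if (edf <= 2) "weakly nonlinear"
         else "nonlinear"
  list(edf = edf, classification = cls)
}

#' Significance of a smooth term
#'
#' Wald-type test of the penalized coefficients of one smooth, as reported
#' by the REML fit (F statistic with edf-based reference degrees of
#' freedom).
#'
#' @inheritParams classify_shape
#' @return Named numeric vector \code{c(edf, ref_df, F, p)}.
#' @export
smooth_significance <- function(fit, term = "age") {
  row <- fit$smooth_table[match_smooth_term(fit, term), ]
  c(edf = row$edf, ref_df = row$ref_df, F = row$F, p = row$p)
}

#' Sex-stratified smooth fits
#'
#' Fits the age smooth separately within each sex (no sex terms), sharing
#' the reporting format, to describe each sex's trajectory without assuming
#' a common reference shape.
#'
#' @inheritParams fit_gamm
#' @return A named list with the \code{female} and \code{male}
#'   \code{smooth_fit}s.
#' @export
stratified_fits <- function(data, region, spec = smooth_spec()) {
  spec$sex_smooth <- FALSE
  out <- lapply(setNames(SEXES, SEXES), function(sx) {
    sub <- data[data$sex == sx, , drop = FALSE]
    if (!nrow(sub[sub$region == region, ])) {
      stop("no ", sx, " observations for region '", region, "'", call. = FALSE)
    }
    fit <- fit_gamm(sub, region, spec)
    fit
  })
  out
}

# Population-level predictions (random subject terms excluded): the basis
# for QC residuals and stratified comparisons.
population_prediction <- function(fit, newdata = NULL) {
  excl <- grep("subject", rownames(fit$smooth_table), value = TRUE)
  as.numeric(mgcv::predict.gam(fit$gam, newdata = newdata %||% fit$data,
                               exclude = excl))
}
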