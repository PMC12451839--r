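#' Structural growth functions
#'
#' Three candidate trajectory shapes for volumetric development across
#' adolescence: a four-parameter logistic capturing S-shaped change, a
#' logarithmic function capturing a decelerating rate of change, and a
#' straight line.
#'
#' The logistic is
#' \deqn{y = A_{lower} + \frac{A_{upper} - A_{lower}}{1 + (x/\mathrm{Inflection})^{-\mathrm{Hill}}}}
#' where \code{a_lower} and \code{a_upper} are the limiting volumes,
#' \code{inflection} (> 0, in years) is the age at which the curve crosses
#' the midpoint of its asymptotes, and \code{hill} is a dimensionless slope
#' parameter whose sign sets the direction of change: \code{hill > 0} moves
#' the curve from \code{a_lower} towards \code{a_upper} with increasing age,
#' \code{hill < 0} the reverse. Note the identifiability symmetry: swapping
#' the asymptotes while negating the hill leaves the curve unchanged; fits
#' resolve it deterministically through initialization (see
#' \code{\link{fit_nlmm}}).
#'
#' The inflection parameter is the age at the asymptote midpoint. On the
#' linear-age scale the age of literal maximum |dy/dx| for this
#' parameterization is slightly offset from it; the parameter itself is what
#' is estimated and reported, and is conventionally read as the age of most
#' rapid volumetric change.
#'
#' The logarithmic model is \eqn{y = a + b\,\ln x} (natural log); \code{a}
#' is the value at age 1 year (outside any plausible study range, so not
#' interpreted) and \code{b} the rate of change per log-year. The linear
#' model is \eqn{y = a + b x}.
#'
#' @param x age in years; must be > 0 for the logistic and logarithmic
#'   functions.
#' @param a_lower,a_upper logistic asymptotes (volume units).
#' @param inflection logistic midpoint age in years (> 0).
#' @param hill logistic slope parameter (dimensionless).
#' @param a intercept parameter (volume units).
#' @param b rate parameter (volume units per year or per log-year).
#' @return Numeric vector of volumes, recycled over \code{x}.
#' @examples
#' eval_logistic(14.52, 5089.72, 6105.41, 14.52, -5.94)  # asymptote midpoint
#' eval_linear(10, 4673.60, -31.00)
#' @name structural_models
NULL

#' @rdname structural_models
#' @export
eval_logistic <- function(x, a_lower, a_upper, inflection, hill) {
  if (any(x <= 0)) stop("eval_logistic: age `x` must be > 0", call. = FALSE)
  if (any(inflection <= 0)) stop("eval_logistic: `inflection` must be > 0", call. = FALSE)
  unname(a_lower + (a_upper - a_lower) / (1 + (x / inflection)^(-hill)))
}

#' @rdname structural_models
#' @export
eval_logarithmic <- function(x, a, b) {
  if (any(x <= 0)) stop("eval_logarithmic: age `x` must be > 0", call. = FALSE)
  unname(a + b * log(x))
}

#' @rdname structural_models
#' @export
eval_linear <- function(x, a, b) {
  unname(a + b * x)
}

# Parameter names per structural function, in canonical order.
structural_params <- function(fun) {
  switch(fun,
    logistic = c("a_lower", "a_upper", "inflection", "hill"),
    logarithmic = c("a", "b"),
    linear = c("a", "b"),
    stop("unknown structural function: ", fun, call. = FALSE)
  )
}

# Evaluate any structural function with a named parameter vector.
eval_structural <- function(fun, x, params) {
  switch(fun,
    logistic = eval_logistic(x, params[["a_lower"]], params[["a_upper"]],
                             params[["inflection"]], params[["hill"]]),
    logarithmic = eval_logarithmic(x, params[["a"]], params[["b"]]),
    linear = eval_linear(x, params[["a"]], params[["b"]]),
    stop("unknown structural function: ", fun, call. = FALSE)
  )
}

# The per-subject scalar of scientific interest for a given function:
# maturational timing (inflection) for the logistic, rate (b) otherwise.
derived_scalar_name <- function(fun) {
  if (fun == "logistic") "inflection" else "b"
}

#' Covariate-to-parameter map
#'
#' Describes which covariates shift which structural growth parameters in a
#' nonlinear mixed model. Sex is coded with female as the reference level, so
#' a sex coefficient is the additive male shift on that parameter; the motion
#' covariate (subject-mean Euler number) enters on its raw scale.
#'
#' @param parameter character vector of structural parameter names.
#' @param covariate character vector (same length) of covariate names
#'   (e.g. \code{"sex"}, \code{"euler"}, \code{"software"}).
#' @return An object of class \code{covariate_map}: a data.frame with columns
#'   \code{parameter} and \code{covariate}.
#' @examples
#' covariate_map(parameter = c("inflection", "hill"),
#'               covariate = c("sex", "euler"))
#' @export
covariate_map <- function(parameter = character(), covariate = character()) {
  stopifnot(length(parameter) == length(covariate))
  cm <- data.frame(parameter = as.character(parameter),
                   covariate = as.character(covariate),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(cm)) {
    stop("covariate_map: each (parameter, covariate) pair may appear at most once",
         call. = FALSE)
  }
  class(cm) <- c("covariate_map", "data.frame")
  cm
}

# Validate a covariate map against a structural function: parameters must
# exist and the entry count must respect the per-function ceiling (8 for the
# logistic, 4 for the two-parameter functions).
validate_covariate_map <- function(cm, fun) {
  pars <- structural_params(fun)
  bad <- setdiff(cm$parameter, pars)
  if (length(bad)) {
    stop("covariate map names unknown parameter(s) for the ", fun,
         " function: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ceiling_n <- if (fun == "logistic") 8L else 4L
  if (nrow(cm) > ceiling_n) {
    stop("covariate map has ", nrow(cm), " entries; at most ", ceiling_n,
         " are allowed for the ", fun, " function", call. = FALSE)
  }
  invisible(cm)
}

#' Assemble individual-level growth parameters
#'
#' Combines population fixed effects, covariate shifts and a subject's random
#' effects into that subject's realized parameter vector:
#' \eqn{\phi_i = \beta + \sum_k b_k z_{ik} + \eta_i} applied per mapped
#' parameter. A female subject with zero motion covariate and zero random
#' effects returns the population vector unchanged (female is the reference
#' level everywhere).
#'
#' @param population named numeric vector of population parameters.
#' @param covariates named numeric vector of the subject's covariate values
#'   (e.g. \code{c(sex = 1)} for a male, \code{c(euler = -150)}).
#' @param map a \code{\link{covariate_map}}.
#' @param coefficients named numeric vector of covariate coefficients, named
#'   \code{"<covariate>.<parameter>"} (e.g. \code{"sex.inflection"}).
#' @param random_effect named numeric vector of subject random effects
#'   (defaults to all zero).
#' @return Named numeric vector of the subject's parameters.
#' @export
individual_params <- function(population, covariates = numeric(), map = covariate_map(),
                              coefficients = numeric(), random_effect = NULL) {
  phi <- population
  if (is.null(random_effect)) random_effect <- setNames(numeric(length(phi)), names(phi))
  if (nrow(map)) {
    for (i in seq_len(nrow(map))) {
      par <- map$parameter[i]
      cov <- map$covariate[i]
      if (!cov %in% names(covariates)) {
        stop("individual_params: missing covariate value for '", cov, "'",
             call. = FALSE)
      }
      key <- paste(cov, par, sep = ".")
      coefv <- if (key %in% names(coefficients)) coefficients[[key]] else 0
      phi[[par]] <- phi[[par]] + coefv * covariates[[cov]]
    }
  }
  phi[names(random_effect)] <- phi[names(random_effect)] + random_effect
  phi
}
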