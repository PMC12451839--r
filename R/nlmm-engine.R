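# Nonlinear mixed-effects estimation engine.
#
# Two estimation paths behind one surface:
#  * logistic: stochastic-approximation EM (SAEM) for global search, then a
#    deterministic quasi-Newton polish of the Gauss-Newton Laplace marginal
#    likelihood. SEs from the numeric observed information of the Laplace
#    objective; log-likelihood for information criteria by importance
#    sampling at the final estimates (Gaussian proposal at the conditional
#    modes), with the Laplace value also reported.
#  * linear / logarithmic: these are linear in their parameters, so the
#    marginal likelihood is Gaussian and exact; fixed effects are profiled
#    out by GLS and the variance parameters optimized directly. No
#    approximation, no Monte Carlo.

#' Structural model specification for NLMM fitting
#'
#' @param fun \code{"logistic"}, \code{"logarithmic"} or \code{"linear"}.
#' @param random_effects structural parameters carrying additive Gaussian
#'   random effects (diagonal covariance); default all of them.
#' @param covariates a \code{\link{covariate_map}} attaching covariates to
#'   structural parameters (at most 8 entries for the logistic, 4 otherwise).
#' @return A list of class \code{structural_spec}.
#' @export
structural_spec <- function(fun = c("logistic", "logarithmic", "linear"),
                            random_effects = NULL,
                            covariates = covariate_map()) {
  fun <- match.arg(fun)
  pn <- structural_params(fun)
  random_effects <- random_effects %||% pn
  stopifnot(length(random_effects) >= 1, all(random_effects %in% pn))
  validate_covariate_map(covariates, fun)
  structure(list(fun = fun, random_effects = random_effects,
                 covariates = covariates, error_model = "constant"),
            class = "structural_spec")
}

#' Estimation settings for \code{\link{fit_nlmm}}
#'
#' @param saem_burnin,saem_smooth SAEM iteration counts for the exploration
#'   phase (step size 1, with simulated-annealing variance guards) and the
#'   smoothing phase (step size 1/k).
#' @param mh_passes random-walk Metropolis passes per SAEM iteration.
#' @param polish logical; run the Laplace quasi-Newton polish after SAEM.
#' @param polish_maxit BFGS iteration cap for the polish.
#' @param is_samples importance-sampling draws per subject for the
#'   log-likelihood used in AIC/BIC (logistic path).
#' @param compute_se logical; compute standard errors.
#' @param n_starts independent SAEM chains (each polished); the run with the
#'   best Laplace marginal likelihood is kept. Two starts guard against the
#'   occasional chain settling on the flat asymptote-spread ridge of the
#'   four-parameter logistic.
#' @return A list of class \code{nlmm_control}.
#' @export
nlmm_control <- function(saem_burnin = 300, saem_smooth = 200, mh_passes = 2,
                         polish = TRUE, polish_maxit = 400,
                         is_samples = 1000, compute_se = TRUE, n_starts = 2) {
  structure(list(saem_burnin = saem_burnin, saem_smooth = saem_smooth,
                 mh_passes = mh_passes, polish = polish,
                 polish_maxit = polish_maxit, is_samples = is_samples,
                 compute_se = compute_se, n_starts = n_starts),
            class = "nlmm_control")
}

# ---- covariate handling ----------------------------------------------------

# Collapse per-visit covariates to one value per subject. Sex is a male
# indicator (female reference); euler and etiv are subject means (the
# covariate model is subject-level); software is the mean ordinal epoch.
subject_covariate_table <- function(df) {
  ids <- unique(df$subject_id)
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  first <- df[match(ids, df$subject_id), ]
  out$sex <- as.numeric(first$sex == "male")
  if ("euler" %in% names(df)) {
    out$euler <- as.numeric(tapply(df$euler, factor(df$subject_id, ids), mean))
  }
  if ("software" %in% names(df)) {
    sw <- suppressWarnings(as.numeric(sub("^sw", "", as.character(df$software))))
    if (anyNA(sw)) sw <- as.numeric(factor(df$software))
    out$software <- as.numeric(tapply(sw, factor(df$subject_id, ids), mean))
  }
  if ("etiv" %in% names(df)) {
    out$etiv <- as.numeric(tapply(df$etiv, factor(df$subject_id, ids), mean))
  }
  out
}

# Fixed-effect bookkeeping: grouped ordering (each structural parameter
# followed by its covariate coefficients, named "<cov>.<param>").
fixed_effect_names <- function(spec) {
  pn <- structural_params(spec$fun)
  unlist(lapply(pn, function(p) {
    covs <- spec$covariates$covariate[spec$covariates$parameter == p]
    c(p, if (length(covs)) paste(covs, sep = ".", p))
  }))
}

# N x q incidence of fixed effects onto the per-subject parameter matrix:
# mu[i, p] = sum over fixed effects gamma_j * M[[p]][i, j].
param_design <- function(spec, covtab) {
  pn <- structural_params(spec$fun)
  fe <- fixed_effect_names(spec)
  N <- nrow(covtab)
  lapply(setNames(pn, pn), function(p) {
    M <- matrix(0, N, length(fe), dimnames = list(NULL, fe))
    M[, p] <- 1
    covs <- spec$covariates$covariate[spec$covariates$parameter == p]
    for (cv in covs) {
      if (!cv %in% names(covtab)) {
        stop("covariate '", cv, "' not present in the dataset", call. = FALSE)
      }
      vals <- covtab[[cv]]
      if (all(is.na(vals))) stop("covariate '", cv, "' is all-missing", call. = FALSE)
      if (anyNA(vals)) {
        stop("missing '", cv, "' value for subject(s) ",
             paste(utils::head(covtab$subject_id[is.na(vals)], 5), collapse = ", "),
             call. = FALSE)
      }
      M[, paste(cv, p, sep = ".")] <- vals
    }
    M
  })
}

mu_from_gamma <- function(Mlist, gamma) {
  vapply(Mlist, function(M) as.numeric(M %*% gamma), numeric(nrow(Mlist[[1]])))
}

# ---- logistic internals ----------------------------------------------------

# analytic Jacobian of the logistic wrt (a_lower, a_upper, inflection, hill)
logistic_jac <- function(x, p) {
  t <- x / p[3]; u <- t^(-p[4]); den <- 1 + u; dA <- p[2] - p[1]
  cbind(u / den, 1 / den,
        -dA / den^2 * u * p[4] / p[3],
        dA / den^2 * u * log(t))
}

flog_mat <- function(x, P, idx) {
  # P: subjects x 4 parameter matrix; idx: row index per observation
  P[idx, 1] + (P[idx, 2] - P[idx, 1]) / (1 + (x / P[idx, 3])^(-P[idx, 4]))
}

# SAEM for the logistic with arbitrary covariate maps and diagonal random
# effects on a subset of parameters. Returns population estimates and the
# final chain state (used to warm-start the Laplace polish).
saem_logistic <- function(y, x, idx, N, Mlist, spec, control, refine_init = TRUE) {
  pn <- structural_params("logistic")
  re <- match(spec$random_effects, pn)
  nobs <- length(y)
  fe <- fixed_effect_names(spec)

  # deterministic data-driven initialization (resolves the asymptote-swap /
  # hill-negation symmetry): asymptotes from the observed range, inflection
  # at the median age, hill sign from the age-volume rank correlation
  beta0 <- c(a_lower = min(y), a_upper = max(y), inflection = stats::median(x),
             hill = if (stats::cor(x, y, method = "spearman") >= 0) 4 else -4)
  nf <- if (refine_init) suppressWarnings(
    try(stats::nls(y ~ a_lower + (a_upper - a_lower) / (1 + (x / inflection)^(-hill)),
                   start = as.list(beta0),
                   control = stats::nls.control(maxiter = 100, warnOnly = TRUE)),
        silent = TRUE)) else try(stop("skipped"), silent = TRUE)
  if (!inherits(nf, "try-error")) {
    cf <- stats::coef(nf)
    if (all(is.finite(cf)) && cf[["inflection"]] > 0 &&
        sign(cf[["hill"]]) == sign(beta0[["hill"]])) beta0 <- cf
  }
  gamma <- setNames(numeric(length(fe)), fe)
  gamma[pn] <- beta0
  mu <- mu_from_gamma(Mlist, gamma)
  omega2 <- setNames(pmax((0.15 * abs(beta0))^2, 1e-8), pn)[re]
  mu_obs <- flog_mat(x, mu, idx)
  sigma2 <- max(mean((y - mu_obs)^2), 1e-10)

  phi <- mu
  rss_of <- function(P) rowsum((y - flog_mat(x, P, idx))^2, idx)[, 1]
  cur <- rss_of(phi)
  ss1 <- phi; ss2 <- phi^2; ssr <- sum(cur)
  rw <- matrix(rep(pmax(abs(beta0[re]) * 0.05, 0.02), each = N), N, length(re))

  K1 <- control$saem_burnin; K2 <- control$saem_smooth
  for (k in seq_len(K1 + K2)) {
    # kernel 1: independent proposals from the current subject-level prior
    prop <- phi
    prop[, re] <- mu[, re] +
      matrix(stats::rnorm(N * length(re), 0, rep(sqrt(omega2), each = N)), N)
    bad <- !is.finite(prop[, 3]) | prop[, 3] <= 0
    prop[bad, 3] <- phi[bad, 3]
    nrss <- rss_of(prop)
    take <- log(stats::runif(N)) < (cur - nrss) / (2 * sigma2)
    phi[take, ] <- prop[take, ]; cur[take] <- nrss[take]
    # kernel 2: componentwise random walks with adapted scales
    for (pass in seq_len(control$mh_passes)) {
      for (jj in seq_along(re)) {
        j <- re[jj]
        prop <- phi
        prop[, j] <- phi[, j] + stats::rnorm(N, 0, rw[, jj])
        if (j == 3) {
          bad <- prop[, 3] <= 0
          prop[bad, 3] <- phi[bad, 3]
        }
        nrss <- rss_of(prop)
        lr <- (cur - nrss) / (2 * sigma2) -
          ((prop[, j] - mu[, j])^2 - (phi[, j] - mu[, j])^2) / (2 * omega2[jj])
        take <- log(stats::runif(N)) < lr
        phi[take, ] <- prop[take, ]; cur[take] <- nrss[take]
        rw[, jj] <- rw[, jj] * ifelse(take, 1.1, 0.97)
      }
    }
    g <- if (k <= K1) 1 else 1 / (k - K1)
    ss1 <- ss1 + g * (phi - ss1)
    ss2 <- ss2 + g * (phi^2 - ss2)
    ssr <- ssr + g * (sum(cur) - ssr)
    # M-step: per-parameter regression of the averaged individual parameters
    # on that parameter's fixed-effect design (closed form for this model)
    for (p in seq_along(pn)) {
      M <- Mlist[[p]]
      use <- colSums(M != 0) > 0
      cf <- solve(crossprod(M[, use, drop = FALSE]),
                  crossprod(M[, use, drop = FALSE], ss1[, p]))
      gamma[use] <- as.numeric(cf)
    }
    mu <- mu_from_gamma(Mlist, gamma)
    om_new <- pmax(colMeans(ss2[, re, drop = FALSE]) -
                     2 * colMeans(mu[, re, drop = FALSE] * ss1[, re, drop = FALSE]) +
                     colMeans(mu[, re, drop = FALSE]^2), 1e-10)
    sg_new <- ssr / nobs
    if (k <= K1) {
      omega2 <- pmax(om_new, 0.95 * omega2)   # annealing guard against early collapse
      sigma2 <- max(sg_new, 0.95 * sigma2)
    } else {
      omega2 <- om_new
      sigma2 <- sg_new
    }
    # non-random parameters track their fixed-effect value exactly
    fixed_pars <- setdiff(seq_along(pn), re)
    if (length(fixed_pars)) phi[, fixed_pars] <- mu[, fixed_pars]
  }
  list(gamma = gamma, omega2 = omega2, sigma2 = sigma2, phi = phi, mu = mu)
}

# Penalized Gauss-Newton solve of the per-subject conditional-mode problem.
laplace_inner <- function(y, x, base, re, D, sg2, eta0) {
  p_re <- length(re)
  mkpar <- function(e) { p <- base; p[re] <- p[re] + e; p }
  h <- function(e) {
    if (!all(is.finite(e))) return(Inf)
    p <- mkpar(e)
    if (p[3] <= 0) return(Inf)
    r <- y - eval_logistic(x, p[1], p[2], p[3], p[4])
    if (!all(is.finite(r))) return(Inf)
    sum(r^2) / (2 * sg2) + sum(e^2 * D) / 2
  }
  solve_from <- function(start) {
    eta <- start; hcur <- h(eta)
    if (!is.finite(hcur)) return(NULL)
    lam <- 1e-4
    for (it in 1:40) {
      p <- mkpar(eta)
      r <- y - eval_logistic(x, p[1], p[2], p[3], p[4])
      J <- logistic_jac(x, p)[, re, drop = FALSE]
      if (!all(is.finite(J))) break
      g <- -crossprod(J, r) / sg2 + D * eta
      if (sqrt(sum(g^2)) < 1e-8 * (1 + abs(hcur))) break
      Hm <- crossprod(J) / sg2 + diag(D, p_re)
      dHm <- diag(Hm)
      moved <- FALSE; done <- FALSE
      for (tries in 1:12) {
        # Hm is PD in exact arithmetic; guard the solve against numerical
        # singularity when a variance component collapses
        st <- tryCatch(-solve(Hm + lam * diag(dHm, p_re), g),
                       error = function(e) NULL)
        if (is.null(st)) { lam <- lam * 6; next }
        en <- eta + as.numeric(st); hn <- h(en)
        if (is.finite(hn) && hn <= hcur) {
          done <- (hcur - hn) < 1e-10 * (1 + abs(hcur))
          eta <- en; hcur <- hn; lam <- max(lam / 4, 1e-8); moved <- TRUE
          break
        }
        lam <- lam * 6
      }
      if (!moved || done) break
    }
    list(eta = eta, h = hcur)
  }
  best <- solve_from(eta0)
  # if the warm start landed worse than the unperturbed origin, redo from zero
  if (is.null(best) || best$h > h(numeric(p_re))) {
    alt <- solve_from(numeric(p_re))
    if (!is.null(alt) && (is.null(best) || alt$h < best$h)) best <- alt
  }
  best
}

# Gauss-Newton Laplace negative marginal log-likelihood factory. Carries
# per-subject conditional modes as warm starts; inner solves are run to
# tight tolerance so values are effectively start-independent.
make_laplace_nll <- function(ylist, xlist, Mlist, spec) {
  pn <- structural_params("logistic")
  re <- match(spec$random_effects, pn)
  p_re <- length(re)
  N <- length(ylist)
  modes <- matrix(0, N, p_re)
  env <- environment()
  nll <- function(th) {
    q <- ncol(Mlist[[1]])
    gamma <- th[1:q]
    om2 <- exp(2 * th[q + seq_len(p_re)])
    sg2 <- exp(2 * th[q + p_re + 1])
    if (!all(is.finite(c(gamma, om2, sg2)))) return(1e10)
    mu <- mu_from_gamma(Mlist, gamma)
    D <- 1 / om2
    ll <- 0
    for (i in seq_len(N)) {
      y <- ylist[[i]]; x <- xlist[[i]]; n <- length(y)
      b <- laplace_inner(y, x, mu[i, ], re, D, sg2, modes[i, ])
      if (is.null(b) || !is.finite(b$h)) return(1e10)
      modes[i, ] <<- b$eta
      p <- mu[i, ]; p[re] <- p[re] + b$eta
      J <- logistic_jac(x, p)[, re, drop = FALSE]
      if (!all(is.finite(J))) return(1e10)
      Hm <- crossprod(J) / sg2 + diag(D, p_re)
      ld <- 2 * sum(log(diag(chol(Hm))))
      ll <- ll - b$h + p_re / 2 * log(2 * pi) - 0.5 * ld -
        n / 2 * log(2 * pi * sg2) - 0.5 * sum(log(2 * pi * om2))
    }
    -ll
  }
  attr(nll, "env") <- env
  nll
}

# Importance-sampled marginal log-likelihood at the final estimates:
# Gaussian proposal centred at each subject's conditional mode with inflated
# Laplace covariance.
is_loglik <- function(ylist, xlist, mu, re, omega2, sigma2, modes, n_samples,
                      inflate = 1.3) {
  N <- length(ylist); p_re <- length(re)
  D <- 1 / omega2
  total <- 0
  for (i in seq_len(N)) {
    y <- ylist[[i]]; x <- xlist[[i]]; n <- length(y)
    p0 <- mu[i, ]; p0[re] <- p0[re] + modes[i, ]
    J <- logistic_jac(x, p0)[, re, drop = FALSE]
    Hm <- crossprod(J) / sigma2 + diag(D, p_re)
    Sig <- inflate^2 * solve(Hm)
    L <- chol(Sig)
    Zs <- matrix(stats::rnorm(n_samples * p_re), n_samples) %*% L
    Et <- sweep(Zs, 2, modes[i, ], "+")
    # log integrand and log proposal density per draw
    P <- matrix(mu[i, ], n_samples, 4, byrow = TRUE)
    P[, re] <- P[, re] + Et
    bad <- P[, 3] <= 0
    Yhat <- matrix(NA_real_, n_samples, n)
    okP <- which(!bad)
    if (length(okP)) {
      for (jcol in seq_len(n)) {
        Yhat[okP, jcol] <- P[okP, 1] + (P[okP, 2] - P[okP, 1]) /
          (1 + (x[jcol] / P[okP, 3])^(-P[okP, 4]))
      }
    }
    rss <- rowSums((matrix(y, n_samples, n, byrow = TRUE) - Yhat)^2)
    logint <- -rss / (2 * sigma2) - n / 2 * log(2 * pi * sigma2) -
      rowSums(sweep(Et^2, 2, 2 * omega2, "/")) - 0.5 * sum(log(2 * pi * omega2))
    logint[bad | !is.finite(logint)] <- -Inf
    logq <- -0.5 * rowSums((Zs %*% solve(L))^2) -
      sum(log(diag(L))) - p_re / 2 * log(2 * pi)
    lw <- logint - logq
    m <- max(lw)
    total <- total + m + log(mean(exp(lw - m)))
  }
  total
}

# symmetric central-difference Hessian (no external dependency)
num_hessian <- function(f, th, h) {
  d <- length(th)
  H <- matrix(NA_real_, d, d)
  f0 <- f(th)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- h[i]
    H[i, i] <- (f(th + 2 * ei) - 2 * f0 + f(th - 2 * ei)) / (4 * h[i]^2)
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- numeric(d); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(th + ei + ej) - f(th + ei - ej) - f(th - ei + ej) + f(th - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# ---- linear / logarithmic exact path ---------------------------------------

# Exact marginal Gaussian ML for the two linear-in-parameters functions.
# Fixed effects are profiled by GLS; variance parameters optimized on the
# log scale.
fit_lmm_exact <- function(y, x, idx, N, Mlist, spec, fun) {
  g <- if (fun == "logarithmic") log(x) else x
  pn <- structural_params(fun)
  re <- match(spec$random_effects, pn)
  fe <- fixed_effect_names(spec)
  q <- length(fe)
  ylist <- split(y, idx)
  glist <- split(g, idx)
  # X_i columns: fixed effect j contributes M[[p]][i, j] * Zcol_p
  Xlist <- lapply(seq_len(N), function(i) {
    Z <- cbind(1, glist[[i]])
    X <- matrix(0, length(ylist[[i]]), q)
    for (p in 1:2) X <- X + outer(Z[, p], Mlist[[p]][i, ])
    X
  })
  Zre <- lapply(seq_len(N), function(i) cbind(1, glist[[i]])[, re, drop = FALSE])

  profile_fit <- function(logpar) {
    om2 <- exp(2 * logpar[seq_along(re)])
    sg2 <- exp(2 * logpar[length(re) + 1])
    if (!all(is.finite(c(om2, sg2))) || sg2 <= 0 || max(om2, sg2) > 1e14) {
      return(list(ll = -1e10))
    }
    XtVX <- matrix(0, q, q); XtVy <- numeric(q)
    Vinv <- vector("list", N); logdet <- 0
    for (i in seq_len(N)) {
      Zi <- Zre[[i]]
      Vi <- Zi %*% (om2 * t(Zi)) + diag(sg2, nrow(Zi))
      ch <- try(chol(Vi), silent = TRUE)
      if (inherits(ch, "try-error")) return(list(ll = -1e10))
      logdet <- logdet + 2 * sum(log(diag(ch)))
      Vii <- chol2inv(ch)
      Vinv[[i]] <- Vii
      XtVX <- XtVX + t(Xlist[[i]]) %*% Vii %*% Xlist[[i]]
      XtVy <- XtVy + t(Xlist[[i]]) %*% Vii %*% ylist[[i]]
    }
    gamma <- solve(XtVX, XtVy)
    quad <- 0
    for (i in seq_len(N)) {
      r <- ylist[[i]] - Xlist[[i]] %*% gamma
      quad <- quad + t(r) %*% Vinv[[i]] %*% r
    }
    nobs <- length(y)
    ll <- -0.5 * (logdet + as.numeric(quad) + nobs * log(2 * pi))
    list(ll = ll, gamma = as.numeric(gamma), XtVX = XtVX, om2 = om2, sg2 = sg2)
  }
  # start from per-subject OLS spread
  ols <- stats::lm.fit(cbind(1, g), y)
  res_sd <- stats::sd(ols$residuals)
  start <- c(log(pmax(abs(ols$coefficients[re]) * 0.1, res_sd * 0.1, 1e-4)),
             log(max(res_sd * 0.8, 1e-4)))
  o <- stats::optim(start, function(lp) -profile_fit(lp)$ll, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-12))
  pf <- profile_fit(o$par)
  gamma <- setNames(pf$gamma, fe)
  se <- sqrt(diag(solve(pf$XtVX)))
  names(se) <- fe
  # EB conditional modes (closed form for Gaussian linear models)
  eta <- matrix(0, N, length(re), dimnames = list(NULL, pn[re]))
  for (i in seq_len(N)) {
    Zi <- Zre[[i]]
    Vi <- Zi %*% (pf$om2 * t(Zi)) + diag(pf$sg2, nrow(Zi))
    r <- ylist[[i]] - Xlist[[i]] %*% gamma
    eta[i, ] <- as.numeric((pf$om2 * t(Zi)) %*% solve(Vi, r))
  }
  list(gamma = gamma, se = se, omega2 = setNames(pf$om2, pn[re]),
       sigma2 = pf$sg2, loglik = pf$ll, eta = eta,
       converged = o$convergence == 0, optim = o)
}

# ---- public fitting surface ------------------------------------------------

#' Fit a nonlinear mixed-effects growth model
#'
#' Maximum-likelihood estimation of a structural growth function with
#' additive Gaussian random effects (diagonal covariance) on a subset of its
#' parameters and optional covariates on any parameter (female is the
#' reference sex; motion enters as the subject-mean Euler number on its raw
#' scale). The logistic is estimated by SAEM followed by a deterministic
#' Laplace polish; the linear and logarithmic functions, being linear in
#' their parameters, are estimated by exact marginal Gaussian maximum
#' likelihood. Standard errors come from the observed information
#' (Laplace-approximated for the logistic, GLS for the others), and the
#' log-likelihood entering AIC/BIC is importance-sampled at the final
#' estimates for the logistic and exact otherwise. Results are reproducible
#' under \code{seed}.
#'
#' AIC and BIC use \eqn{k} = number of fixed effects + random-effect
#' variances + 1 (residual variance), and BIC uses \eqn{\ln(n_{subjects})}:
#' the subject count is the effective sample size for between-subject
#' parameters.
#'
#' @param data a \code{\link{long_volumes}} dataset.
#' @param region region to fit.
#' @param spec a \code{\link{structural_spec}}.
#' @param seed integer seed for the stochastic estimation steps.
#' @param control a \code{\link{nlmm_control}}.
#' @return An object of class \code{population_fit}: estimates, standard
#'   errors, \code{cv_percent}, Wald p-values for covariate coefficients,
#'   random-effect variances (\code{omega2}), \code{residual_sd},
#'   \code{loglik} (used in criteria) with \code{loglik_laplace} alongside
#'   for the logistic path, \code{aic}, \code{bic}, counts, and a
#'   \code{convergence} record.
#' @export
fit_nlmm <- function(data, region, spec, seed = 1L,
                     control = nlmm_control()) {
  stopifnot(inherits(data, "long_volumes"), inherits(spec, "structural_spec"))
  df <- data[data$region == region, , drop = FALSE]
  if (!nrow(df)) stop("no observations for region '", region, "'", call. = FALSE)
  ids <- unique(df$subject_id)
  N <- length(ids)
  if (N < 2) stop("need at least 2 subjects", call. = FALSE)
  validate_covariate_map(spec$covariates, spec$fun)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  idx <- match(df$subject_id, ids)
  y <- df$volume; x <- df$age
  covtab <- subject_covariate_table(df)
  Mlist <- param_design(spec, covtab)
  fe <- fixed_effect_names(spec)
  pn <- structural_params(spec$fun)
  re <- match(spec$random_effects, pn)

  if (spec$fun %in% c("linear", "logarithmic")) {
    lf <- fit_lmm_exact(y, x, idx, N, Mlist, spec, spec$fun)
    gamma <- lf$gamma; se <- lf$se
    omega2 <- lf$omega2; sigma2 <- lf$sigma2
    loglik <- lf$loglik; loglik_laplace <- lf$loglik  # exact for this path
    eta <- lf$eta
    convergence <- list(converged = lf$converged, method = "exact-marginal-ML",
                        message = if (lf$converged) "converged" else "optim did not converge")
  } else {
    ylist <- split(y, factor(idx, seq_len(N)))
    xlist <- split(x, factor(idx, seq_len(N)))
    nll <- make_laplace_nll(ylist, xlist, Mlist, spec)
    env <- attr(nll, "env")

    run_one <- function(chain_seed, refine_init = TRUE) {
      set.seed(chain_seed)
      sm <- saem_logistic(y, x, idx, N, Mlist, spec, control, refine_init)
      sm_modes <- sm$phi[, re, drop = FALSE] - sm$mu[, re, drop = FALSE]
      reset_modes <- function() assign("modes", sm_modes, envir = env)
      reset_modes()
      th0 <- c(sm$gamma, 0.5 * log(pmax(sm$omega2, 1e-8)), 0.5 * log(sm$sigma2))
      th <- th0; polished <- FALSE; conv_ok <- !control$polish
      if (control$polish) {
        ps <- c(pmax(abs(sm$gamma), 1), rep(0.5, length(re) + 1))
        gr <- function(th) {
          # forward-difference gradient (one extra evaluation per dimension)
          f0 <- nll(th)
          vapply(seq_along(th), function(j) {
            hj <- 1e-5 * ps[j]
            thj <- th; thj[j] <- thj[j] + hj
            (nll(thj) - f0) / hj
          }, numeric(1))
        }
        o <- try(stats::optim(th0, nll, gr = gr, method = "BFGS",
                              control = list(maxit = control$polish_maxit,
                                             reltol = 1e-8, parscale = ps)),
                 silent = TRUE)
        if (!inherits(o, "try-error") && is.finite(o$value) && all(is.finite(o$par))) {
          # compare the SAEM point and the polished point on fresh
          # evaluations from the same warm start, so inner-solver state
          # cannot bias the call
          reset_modes(); v0 <- nll(th0)
          reset_modes(); v1 <- nll(o$par)
          if (v1 <= v0 + 1e-6 * (1 + abs(v0))) {
            th <- o$par; polished <- TRUE
            conv_ok <- o$convergence == 0
          }
        }
      }
      reset_modes()
      list(th = th, value = nll(th), polished = polished, conv_ok = conv_ok,
           sm_modes = sm_modes, reset_modes = reset_modes)
    }

    # chain 1 starts from the least-squares-refined initialization, later
    # chains from the raw data-driven one, so starts genuinely differ
    runs <- lapply(seq_len(max(1L, control$n_starts)), function(cs) {
      run_one(seed + (cs - 1L) * 7919L, refine_init = cs == 1L)
    })
    best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
    th <- best$th
    polished <- best$polished
    conv_ok <- best$conv_ok
    reset_modes <- best$reset_modes
    q <- length(fe)
    gamma <- setNames(unname(th[1:q]), fe)
    omega2 <- setNames(unname(exp(2 * th[q + seq_along(re)])), pn[re])
    sigma2 <- unname(exp(2 * th[q + length(re) + 1]))

    # final conditional modes at the estimate
    reset_modes()
    nll_final <- nll(th)
    eta <- get("modes", envir = env)
    colnames(eta) <- pn[re]
    mu <- mu_from_gamma(Mlist, gamma)
    loglik_laplace <- -nll_final
    set.seed(seed + 999983L)  # IS draws independent of the chain count
    loglik <- is_loglik(ylist, xlist, mu, re, omega2, sigma2, eta,
                        control$is_samples)

    se <- setNames(rep(NA_real_, q), fe)
    se_ok <- FALSE
    if (control$compute_se) {
      hstep <- c(pmax(abs(gamma) * 1e-3, 1e-4), rep(1e-3, length(re) + 1))
      H <- try(num_hessian(nll, th, hstep), silent = TRUE)
      if (!inherits(H, "try-error") && all(is.finite(H))) {
        Vfull <- try(solve(H), silent = TRUE)
        if (!inherits(Vfull, "try-error") && all(diag(Vfull)[1:q] > 0)) {
          se <- setNames(sqrt(diag(Vfull)[1:q]), fe)
          se_ok <- TRUE
        }
      }
    }
    convergence <- list(converged = conv_ok, method = "SAEM+Laplace-polish",
                        polished = polished,
                        se_available = se_ok,
                        message = if (conv_ok) "converged" else
                          "BFGS polish did not report convergence; estimates from best visited point")
    if (control$compute_se && !se_ok) {
      warning("information matrix singular or not computable; SEs unavailable")
    }
  }

  k <- length(fe) + length(re) + 1
  cvp <- cv_percent(gamma, se)
  is_cov <- grepl("\\.", fe)
  wald_p <- ifelse(is_cov, 2 * stats::pnorm(-abs(gamma / se)), NA_real_)
  names(wald_p) <- fe

  fit <- structure(list(
    region = region, fun = spec$fun, spec = spec,
    estimates = gamma, standard_errors = se,
    cv_percent = cvp, wald_p = wald_p,
    omega2 = omega2, residual_sd = sqrt(sigma2),
    loglik = as.numeric(loglik), loglik_laplace = as.numeric(loglik_laplace),
    k = k, n_subjects = N, n_obs = length(y),
    aic = -2 * as.numeric(loglik) + 2 * k,
    bic = -2 * as.numeric(loglik) + k * log(N),
    convergence = convergence,
    eb_eta = eta, subject_ids = ids, covtab = covtab,
    rescale = attr(data, "rescale")[region],
    seed = seed
  ), class = "population_fit")
  fit
}

#' @export
print.population_fit <- function(x, ...) {
  cat("<population_fit> ", x$fun, " model, region ", x$region, "\n", sep = "")
  cat("  ", x$n_obs, " obs / ", x$n_subjects, " subjects; logLik ",
      round(x$loglik, 2), ", AIC ", round(x$aic, 2), ", BIC ",
      round(x$bic, 2), "\n", sep = "")
  tab <- data.frame(Estimate = round(x$estimates, 4),
                    SE = round(x$standard_errors, 4),
                    `CV%` = round(x$cv_percent, 2),
                    p = signif(x$wald_p, 3), check.names = FALSE)
  print(tab)
  cat("  random-effect SDs:",
      paste(sprintf("%s %.4g", names(x$omega2), sqrt(x$omega2)), collapse = ", "),
      "; residual SD", round(x$residual_sd, 4), "\n")
  invisible(x)
}

#' Coefficient of variation of an estimate
#'
#' CV\% = 100 |SE / estimate|. Values below 20\% are conventionally taken to
#' indicate adequate estimation precision; the gate is strict (\code{cv <
#' 20}), so exactly 20\% fails. A zero estimate has no defined CV and is
#' reported as \code{NA} (not gateable).
#'
#' @param estimate,se numeric vectors.
#' @return \code{cv_percent}: numeric CV in percent. \code{cv_gate}: logical,
#'   \code{TRUE} when the parameter passes the precision gate.
#' @examples
#' cv_percent(5089.72, 57.63)  # 1.13
#' @export
cv_percent <- function(estimate, se) {
  out <- ifelse(estimate == 0, NA_real_, 100 * abs(se / estimate))
  out
}

#' @rdname cv_percent
#' @export
cv_gate <- function(estimate, se) {
  cv <- cv_percent(estimate, se)
  !is.na(cv) & cv < 20
}

#' Information criteria of a fitted model
#'
#' AIC = -2 logLik + 2k and BIC = -2 logLik + k ln(n_subjects), with k the
#' number of estimated quantities (fixed effects + random-effect variances +
#' residual variance). Criteria are only comparable between models fitted to
#' the same response on the same scale.
#'
#' @param fit a \code{population_fit}, or a numeric log-likelihood.
#' @param k,n_subjects used when \code{fit} is a bare log-likelihood.
#' @return Named numeric vector \code{c(aic = , bic = )}.
#' @export
information_criteria <- function(fit, k = NULL, n_subjects = NULL) {
  if (inherits(fit, "population_fit")) {
    ll <- fit$loglik; k <- fit$k; n_subjects <- fit$n_subjects
  } else {
    ll <- fit
  }
  c(aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(n_subjects))
}

#' Empirical-Bayes individual growth parameters
#'
#' Per-subject parameter vectors at the conditional modes of the random
#' effects given the population fit (covariate-adjusted population value +
#' the subject's mode), together with the derived scalar of interest:
#' the inflection point for the logistic, the rate parameter b otherwise.
#' Subjects with few observations shrink towards their covariate-adjusted
#' population values.
#'
#' @param fit a \code{population_fit}.
#' @param data the dataset the fit was computed on (used only for
#'   per-subject observation counts).
#' @return An object of class \code{individual_fit}: a data.frame with one
#'   row per subject (parameters, derived scalar, sex, n_obs).
#' @export
individual_estimates <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "population_fit"))
  pn <- structural_params(fit$fun)
  mu <- mu_from_gamma(param_design(fit$spec, fit$covtab), fit$estimates)
  colnames(mu) <- pn
  phi <- mu
  phi[, colnames(fit$eb_eta)] <- phi[, colnames(fit$eb_eta)] + fit$eb_eta
  scalar <- derived_scalar_name(fit$fun)
  n_obs <- if (!is.null(data)) {
    d <- data[data$region == fit$region, ]
    as.integer(table(factor(d$subject_id, fit$subject_ids)))
  } else NA_integer_
  out <- data.frame(subject_id = fit$subject_ids,
                    sex = ifelse(fit$covtab$sex == 1, "male", "female"),
                    phi, derived = phi[, scalar], n_obs = n_obs,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "scalar") <- scalar
  attr(out, "fun") <- fit$fun
  class(out) <- c("individual_fit", "data.frame")
  out
}

#' Population and individual predictions with fit diagnostics
#'
#' For every observation: the population prediction (random effects at zero,
#' covariates applied) and the individual prediction (empirical-Bayes
#' parameters). Summarizes each by the slope and intercept of
#' observed ~ predicted (identity indicates good fit) and reports a
#' clustering index for the individual predictions — the between-cluster to
#' total variance ratio from a 2-means split — as a numeric counterpart of
#' the banding visible in diagnostic plots of poorly fitting models
#' (threshold-free; larger means more clustered).
#'
#' @param fit a \code{population_fit}.
#' @param individual an \code{\link{individual_estimates}} result (computed
#'   if missing).
#' @param data the dataset the fit was computed on.
#' @return A list with the per-observation table and the summary statistics.
#' @export
predicted_vs_observed <- function(fit, data, individual = NULL) {
  stopifnot(inherits(fit, "population_fit"))
  individual <- individual %||% individual_estimates(fit, data)
  df <- data[data$region == fit$region, ]
  pn <- structural_params(fit$fun)
  mu <- mu_from_gamma(param_design(fit$spec, fit$covtab), fit$estimates)
  colnames(mu) <- pn
  i <- match(df$subject_id, fit$subject_ids)
  pop_pred <- vapply(seq_len(nrow(df)), function(j)
    eval_structural(fit$fun, df$age[j], as.list(mu[i[j], ])), numeric(1))
  phi <- as.matrix(individual[, pn])
  ind_pred <- vapply(seq_len(nrow(df)), function(j)
    eval_structural(fit$fun, df$age[j], as.list(setNames(phi[i[j], ], pn))), numeric(1))
  lm_pop <- stats::coef(stats::lm(df$volume ~ pop_pred))
  lm_ind <- stats::coef(stats::lm(df$volume ~ ind_pred))
  km <- stats::kmeans(ind_pred, centers = 2, nstart = 5)
  clustering <- km$betweenss / km$totss
  list(table = data.frame(subject_id = df$subject_id, wave = df$wave,
                          age = df$age, observed = df$volume,
                          population = pop_pred, individual = ind_pred),
       population_line = c(intercept = unname(lm_pop[1]), slope = unname(lm_pop[2])),
       individual_line = c(intercept = unname(lm_ind[1]), slope = unname(lm_ind[2])),
       clustering_index = clustering)
}

#' Flag individual timing estimates outside the observed age range
#'
#' When the derived individual scalar is an age (the logistic inflection
#' point), subjects whose estimate falls outside the observed age range are
#' listed with their observation counts — estimates extrapolated beyond the
#' sampled ages deserve inspection, especially for subjects with three or
#' fewer observations.
#'
#' @param individual an \code{\link{individual_estimates}} result.
#' @param age_range length-2 numeric, the observed age range.
#' @return A data.frame of flagged subjects (possibly empty) with their
#'   estimate and n_obs.
#' @export
flag_out_of_range <- function(individual, age_range) {
  stopifnot(length(age_range) == 2)
  out <- individual[individual$derived < age_range[1] |
                      individual$derived > age_range[2],
                    c("subject_id", "sex", "derived", "n_obs")]
  rownames(out) <- NULL
  out
}
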