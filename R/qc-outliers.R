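# Residual-based longitudinal quality control. An age-sex adjustment GAMM
# (age smooth + sex + age-by-sex difference smooth + subject random
# intercept) is fitted per region; residuals are taken against the
# population-level prediction (random intercept excluded), so a subject
# whose whole series is shifted shows up in their mean residual rather than
# being absorbed by the random intercept.

#' Detect statistical outliers on adjustment-model residuals
#'
#' Two complementary rules at a common threshold (default 2 SD):
#' \emph{between-subject}: subjects whose mean residual deviates from the
#' across-subject mean of subject-mean residuals by at least
#' \code{threshold_sd} times the across-subject SD of those means;
#' \emph{within-subject}: observations deviating from their own subject's
#' mean residual by at least \code{threshold_sd} times the pooled
#' within-subject residual SD. Flags mark records for inspection; nothing is
#' removed unless \code{exclude = TRUE}. Subjects with a single observation
#' are skipped by the within-subject rule (noted in the report).
#'
#' @param data a \code{\link{long_volumes}} dataset.
#' @param region region to screen.
#' @param threshold_sd flagging threshold in SD units (default 2).
#' @param spec adjustment-model specification (defaults to the standard
#'   age + sex + age-by-sex + random-intercept GAMM).
#' @param exclude logical; if TRUE, also return the dataset with flagged
#'   records removed.
#' @return An object of class \code{outlier_report}: \code{flags} (data.frame
#'   with subject, wave, kind, z), \code{threshold}, counts, and optionally
#'   \code{cleaned}.
#' @export
detect_outliers <- function(data, region, threshold_sd = 2,
                            spec = smooth_spec(), exclude = FALSE) {
  stopifnot(inherits(data, "long_volumes"), threshold_sd > 0)
  fit <- fit_gamm(data, region, spec)
  df <- fit$data
  res <- df$volume - population_prediction(fit)

  ids <- unique(df$subject_id)
  fid <- factor(df$subject_id, ids)
  subj_mean <- tapply(res, fid, mean)
  n_i <- tabulate(fid)

  # between-subject rule: subject means vs their across-subject spread
  # a spread indistinguishable from numerical noise is treated as zero so
  # that an (essentially) perfectly fitting adjustment model yields no flags
  eps <- 1e-8 * mean(abs(df$volume))
  mu_b <- mean(subj_mean)
  sd_b <- stats::sd(subj_mean)
  z_b <- if (sd_b > eps) (subj_mean - mu_b) / sd_b else subj_mean * 0
  flag_b <- abs(z_b) >= threshold_sd

  # within-subject rule: deviations from own mean, pooled within-subject SD
  centered <- res - subj_mean[as.integer(fid)]
  multi <- n_i[as.integer(fid)] > 1
  sd_w <- sqrt(sum(centered[multi]^2) / max(sum(multi) - sum(n_i > 1), 1))
  z_w <- if (sd_w > eps) ifelse(multi, centered / sd_w, NA_real_)
         else ifelse(multi, 0, NA_real_)
  flag_w <- !is.na(z_w) & abs(z_w) >= threshold_sd

  flags <- rbind(
    if (any(flag_b)) data.frame(subject_id = ids[flag_b], wave = NA_integer_,
                                region = region, kind = "between_subject",
                                z = as.numeric(z_b[flag_b])),
    if (any(flag_w)) data.frame(subject_id = df$subject_id[flag_w],
                                wave = df$wave[flag_w], region = region,
                                kind = "within_subject",
                                z = as.numeric(z_w[flag_w]))
  )
  if (is.null(flags)) {
    flags <- data.frame(subject_id = character(), wave = integer(),
                        region = character(), kind = character(), z = numeric())
  }
  out <- structure(list(
    flags = flags, threshold = threshold_sd, region = region,
    n_between = sum(flag_b), n_within = sum(flag_w),
    n_singleton_skipped = sum(n_i == 1),
    n_obs = nrow(df), n_subjects = length(ids),
    residual_sd_within = sd_w, subject_mean_sd = sd_b
  ), class = "outlier_report")
  if (exclude) {
    drop_subj <- unique(flags$subject_id[flags$kind == "between_subject"])
    drop_rec <- flags$kind == "within_subject"
    keep <- !(data$region == region &
                (data$subject_id %in% drop_subj |
                   paste(data$subject_id, data$wave) %in%
                     paste(flags$subject_id[drop_rec], flags$wave[drop_rec])))
    out$cleaned <- long_volumes(data[keep, , drop = FALSE])
  }
  out
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> region ", x$region, ", threshold ", x$threshold,
      " SD\n  ", x$n_between, " between-subject flag(s), ", x$n_within,
      " within-subject flag(s) over ", x$n_obs, " obs / ", x$n_subjects,
      " subjects\n", sep = "")
  if (x$n_singleton_skipped) {
    cat("  ", x$n_singleton_skipped,
        " single-observation subject(s) skipped by the within-subject rule\n",
        sep = "")
  }
  if (nrow(x$flags)) print(x$flags)
  invisible(x)
}
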