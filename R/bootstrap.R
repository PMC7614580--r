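#' Nonparametric bootstrap confidence intervals over individuals
#'
#' Resamples individuals (not rows) with replacement, so that all of an
#' individual's person-periods and trial appearances travel together, and
#' re-runs the entire estimation pipeline — trial formation, weight-model
#' fitting, MSM fitting, standardization — in each resample.  Percentile
#' intervals use the default type-7 empirical quantile at levels
#' (1-level)/2 and 1-(1-level)/2.  Per-resample seeds are split from the
#' master seed by a counter so any subset of resamples is reproducible.
#'
#' @param cohort a \code{longitudinal_cohort}.
#' @param statistic function(cohort) returning a named numeric vector of
#'   estimates (e.g. risk differences at several horizons); see
#'   [estimate_msm_iptw()] / [estimate_seq_trials()] for building blocks.
#' @param B number of bootstrap resamples (>= 2).
#' @param level confidence level in (0, 1).
#' @param seed integer master seed.
#' @param identity_resample if TRUE, every "resample" is the original
#'   sample (degenerate intervals at the point estimate; for testing).
#' @return list with \code{estimate} (on the original sample),
#'   \code{lower}, \code{upper}, the resample matrix \code{reps}
#'   (B_used x n_stat), and \code{n_failed}.
#' @export
bootstrap_ci <- function(cohort, statistic, B = 1000, level = 0.95,
                         seed = NULL, identity_resample = FALSE) {
  stopifnot(B >= 2, level > 0, level < 1)
  est <- statistic(cohort)
  n <- nrow(cohort)
  K <- n_visits(cohort)
  tau <- admin_censor_time(cohort)
  reps <- matrix(NA_real_, B, length(est),
                 dimnames = list(NULL, names(est)))
  base_seed <- if (is.null(seed)) sample.int(2^30, 1) else as.integer(seed)
  for (b in seq_len(B)) {
    set.seed((base_seed + b) %% .Machine$integer.max)
    idx <- if (identity_resample) seq_len(n)
           else sample.int(n, n, replace = TRUE)
    res <- as.data.frame(cohort)[idx, , drop = FALSE]
    res$id <- seq_len(n)
    rcoh <- longitudinal_cohort(res, K = K, admin_censor_time = tau)
    val <- tryCatch(statistic(rcoh), error = function(e) NULL)
    if (!is.null(val)) reps[b, ] <- val
  }
  ok <- stats::complete.cases(reps)
  if (mean(!ok) > 0.10)
    stop("more than 10% of bootstrap resamples failed (",
         sum(!ok), " of ", B, ")")
  reps <- reps[ok, , drop = FALSE]
  alpha <- (1 - level) / 2
  lower <- apply(reps, 2, stats::quantile, probs = alpha, type = 7)
  upper <- apply(reps, 2, stats::quantile, probs = 1 - alpha, type = 7)
  list(estimate = est, lower = lower, upper = upper, reps = reps,
       n_failed = sum(!ok), level = level)
}
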