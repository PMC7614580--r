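#' Run a replicated simulation study comparing the two estimators
#'
#' For each replicate: simulate a cohort under the scenario, run the
#' requested estimation methods, and record the standardized survival
#' probabilities under "always treated" and "never treated" and their risk
#' difference at the requested horizons, plus the largest weight per time
#' period.  Per-replicate seeds are derived from the master seed by a
#' counter so that any subset of replicates is independently reproducible.
#' Replicates in which an estimator fails are excluded and counted.
#'
#' @param scenario preset name (see [scenario_params()]) or a
#'   \code{scenario_params} object.
#' @param n individuals per replicate.
#' @param n_reps number of replicates.
#' @param methods subset of \code{c("msm_iptw", "seq_trials")}.
#' @param seed integer master seed.
#' @param taus evaluation horizons.
#' @param conditional_L0 MSM-IPTW variant (see [estimate_msm_iptw()]).
#' @param model \code{"aalen"} or \code{"cox"}.
#' @param truncate_percentile optional weight-truncation percentile.
#' @return object of class \code{st_study}: list with \code{estimates}
#'   (long data.frame: rep, method, quantity, tau, value),
#'   \code{max_weights} (rep, method, period, max_weight),
#'   \code{n_failed}, and the study configuration.
#' @export
run_study <- function(scenario, n = 5000, n_reps = 200,
                      methods = c("msm_iptw", "seq_trials"),
                      seed = 1, taus = 1:5, conditional_L0 = TRUE,
                      model = "aalen", truncate_percentile = NULL) {
  params <- if (inherits(scenario, "scenario_params")) scenario
            else scenario_params(scenario)
  methods <- match.arg(methods, c("msm_iptw", "seq_trials"), several.ok = TRUE)
  est_rows <- vector("list", n_reps)
  w_rows <- vector("list", n_reps)
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- (as.integer(seed) + 104729L * r) %% .Machine$integer.max
    cohort <- simulate_cohort(params, n, seed = rep_seed)
    e_list <- list(); w_list <- list()
    ok <- TRUE
    for (m in methods) {
      fit <- tryCatch(
        if (m == "msm_iptw")
          estimate_msm_iptw(cohort, taus, conditional_L0 = conditional_L0,
                            model = model,
                            truncate_percentile = truncate_percentile)
        else
          estimate_seq_trials(cohort, taus, model = model,
                              truncate_percentile = truncate_percentile),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      e_list[[m]] <- data.frame(
        rep = r, method = m,
        quantity = rep(c("S1", "S0", "RD"), each = length(taus)),
        tau = rep(taus, 3L),
        value = c(fit$S1, fit$S0, fit$RD))
      mw <- fit$max_weights
      w_list[[m]] <- data.frame(rep = r, method = m, period = mw$period,
                                max_weight = mw$max_weight)
    }
    if (!ok) { n_failed <- n_failed + 1L; next }
    est_rows[[r]] <- do.call(rbind, e_list)
    w_rows[[r]] <- do.call(rbind, w_list)
  }
  structure(list(estimates = do.call(rbind, est_rows),
                 max_weights = do.call(rbind, w_rows),
                 n_failed = n_failed,
                 scenario = params, n = n, n_reps = n_reps,
                 methods = methods, taus = taus, seed = seed),
            class = "st_study")
}

#' Summarize study performance against the truth
#'
#' Monte-Carlo mean, empirical SD across replicates, bias = mean - truth,
#' Monte-Carlo error of the mean (SD / sqrt(n_reps)) per (method, quantity,
#' horizon), plus — when both methods are present — the relative efficiency
#' of the sequential-trials analysis versus MSM-IPTW for the risk
#' difference, defined as the inverse of the ratio of the empirical
#' variances: Var(RD, MSM-IPTW) / Var(RD, sequential trials).  Values above
#' 1 mean the sequential-trials estimate is the more efficient one.
#'
#' @param study an \code{st_study} (or its \code{estimates} data.frame).
#' @param truth a \code{truth_curves} object whose grid contains the study
#'   horizons.
#' @return list with \code{performance} (method, quantity, tau, mean, sd,
#'   bias, mc_error, n_reps) and \code{relative_efficiency} (tau, value;
#'   NULL with fewer than two methods).
#' @export
performance_summary <- function(study, truth) {
  est <- if (inherits(study, "st_study")) study$estimates else study
  if (is.null(est) || !all(c("method", "quantity", "tau", "value") %in% names(est)))
    stop("no usable estimates")
  sp <- split(est, list(est$method, est$quantity, est$tau), drop = TRUE)
  perf <- do.call(rbind, lapply(sp, function(d) {
    if (nrow(d) < 2) stop("need >= 2 replicates per cell")
    tv <- truth_at(truth, d$tau[1L], what = d$quantity[1L])
    data.frame(method = d$method[1L], quantity = d$quantity[1L],
               tau = d$tau[1L], mean = mean(d$value),
               sd = stats::sd(d$value), bias = mean(d$value) - tv,
               mc_error = stats::sd(d$value) / sqrt(nrow(d)),
               n_reps = nrow(d))
  }))
  rownames(perf) <- NULL
  perf <- perf[order(perf$method, perf$quantity, perf$tau), ]
  re <- NULL
  if (all(c("msm_iptw", "seq_trials") %in% est$method)) {
    rd <- est[est$quantity == "RD", ]
    re <- do.call(rbind, lapply(sort(unique(rd$tau)), function(tt) {
      v_i <- stats::var(rd$value[rd$method == "msm_iptw" & rd$tau == tt])
      v_s <- stats::var(rd$value[rd$method == "seq_trials" & rd$tau == tt])
      data.frame(tau = tt, relative_efficiency = v_i / v_s)
    }))
  }
  list(performance = perf, relative_efficiency = re)
}

#' Largest weight by period across replicates
#'
#' Reshapes the per-replicate weight maxima recorded by [run_study()] into
#' one row per (method, replicate, period) — the surface for comparing how
#' extreme the IPTW get relative to the IPACW over follow-up time.  For the
#' sequential-trials analysis the period is time since trial start, and the
#' IPACW are exactly 1 in period 0.
#'
#' @param study an \code{st_study}.
#' @return data.frame \code{method, rep, period, max_weight}.
#' @export
max_weight_summary <- function(study) {
  mw <- study$max_weights
  mw[order(mw$method, mw$rep, mw$period),
     c("method", "rep", "period", "max_weight")]
}
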