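#' Build the stack of emulated sequential trials
#'
#' A trial is formed at each visit k.  Individuals alive and under
#' observation at visit k who meet the eligibility criterion (untreated at
#' all of the previous \code{washout} visits; the default washout covers the
#' full history, so eligibility is no prior treatment at all) enter trial k
#' with arm equal to their observed treatment at k: "initiators"
#' (\code{arm = 1}) versus "non-initiators" (\code{arm = 0}).  Non-initiators
#' in trial k can appear as initiators in a later trial; initiators appear
#' in only one trial.  Follow-up within a trial is measured from the trial
#' start (t = time - k), so later trials have shorter maximum follow-up
#' unless \code{horizon} imposes a common fixed length.
#'
#' The returned stack is *uncensored*: it contains one row per within-trial
#' visit interval survived to, including intervals after a treatment
#' deviation.  Use [apply_artificial_censoring()] to cut follow-up at the
#' first deviation from the arm (the rows removed there are still needed
#' beforehand to fit the artificial-censoring models, see
#' [fit_ipacw_models()]).
#'
#' @param cohort a \code{longitudinal_cohort}.
#' @param washout number of prior visits required untreated (default: all).
#' @param k_star depth of trial-baseline covariate history carried as
#'   columns \code{L_base} (= L at the trial visit), \code{L_base_lag1}, ...
#'   Lags before the first visit are set to 0.
#' @param horizon optional common follow-up length per trial (equal-length
#'   trials); default \code{NULL} lets trial k run to the administrative end.
#' @param extra_cols time-fixed cohort columns to carry over.
#' @return a \code{trial_stack} data.frame with columns \code{id, trial,
#'   arm, j, tstart, tstop, Y, A, A_prev, L, L_base (, L_base_lag*)}.
#' @export
build_trials <- function(cohort, washout = Inf, k_star = 0L, horizon = NULL,
                         extra_cols = character()) {
  stopifnot(k_star >= 0, washout >= 0)
  K <- n_visits(cohort)
  pp <- to_person_period(cohort, n_lags_A = 0L, extra_cols = extra_cols)
  A <- treatment_matrix(cohort)
  L <- covariate_matrix(cohort)
  row_of <- match(pp$id, cohort$id)
  out <- vector("list", K)
  for (tk in 0:(K - 1)) {
    # eligibility at visit tk: alive (a row at k = tk exists) and untreated
    # over the washout window [tk - washout, tk - 1]
    lo <- max(0L, tk - as.integer(min(washout, tk)))
    elig_id <- cohort$id[visits_survived(cohort) > tk]
    if (tk > 0) {
      prior <- A[, seq(lo + 1L, tk), drop = FALSE]
      untreated <- rowSums(prior == 1, na.rm = TRUE) == 0
      elig_id <- intersect(elig_id, cohort$id[untreated])
    }
    sel <- pp$id %in% elig_id & pp$k >= tk
    if (!any(sel)) next
    tr <- pp[sel, c("id", "k", "tstop", "Y", "A", "A_prev", "L", extra_cols)]
    ri <- row_of[sel]
    tr$trial <- tk
    tr$arm <- A[ri, tk + 1L]
    tr$j <- tr$k - tk
    tr$tstart <- as.numeric(tr$j)
    tr$tstop <- tr$tstop - tk
    tr$L_base <- L[ri, tk + 1L]
    if (k_star > 0) for (s in seq_len(k_star))
      tr[[paste0("L_base_lag", s)]] <-
        if (tk - s >= 0) L[ri, tk - s + 1L] else 0
    if (!is.null(horizon)) {
      tr <- tr[tr$tstart < horizon, , drop = FALSE]
      over <- tr$tstop > horizon
      tr$tstop[over] <- horizon
      tr$Y[over] <- 0L
    }
    out[[tk + 1L]] <- tr
  }
  stack <- do.call(rbind, out)
  rownames(stack) <- NULL
  cols <- c("id", "trial", "arm", "j", "tstart", "tstop", "Y", "A", "A_prev",
            "L", "L_base", grep("^L_base_lag", names(stack), value = TRUE),
            extra_cols)
  stack <- stack[order(stack$trial, match(stack$id, cohort$id), stack$j), cols]
  rownames(stack) <- NULL
  class(stack) <- c("trial_stack", "data.frame")
  stack
}

#' Artificially censor trial follow-up at treatment deviation
#'
#' Within each trial record, follow-up is cut at the earliest visit m after
#' the trial start at which the observed treatment differs from the arm
#' assigned at trial baseline.  The interval row starting at the deviation
#' visit (and all later rows) are removed, so events after the deviation do
#' not count in that trial; events occurring before the deviation are kept.
#' Under absorbing treatment the initiator arm can never deviate.
#'
#' @param trials an uncensored \code{trial_stack} from [build_trials()].
#' @return the censored \code{trial_stack}.
#' @export
apply_artificial_censoring <- function(trials) {
  # a row deviates if the observed treatment entering its interval differs
  # from the arm; removing every deviated row cuts follow-up at the first
  # deviation visit because treatment deviation is monotone within a trial
  # (arm 0: A jumps to 1 and stays; arm 1: A drops to 0 and stays untreated
  # history is impossible under eligibility, but the rule is general)
  dev <- trials$A != trials$arm
  key <- paste(trials$id, trials$trial, sep = "\r")
  # general (non-monotone) case: censor at the *first* deviation visit
  first_dev <- tapply(ifelse(dev, trials$j, Inf), key, min)
  cut <- as.numeric(first_dev[key])
  keep <- trials$j < cut
  out <- trials[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trial_stack", "data.frame")
  out
}
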