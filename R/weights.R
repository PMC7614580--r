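#' Fit treatment-process models for stabilized IPTW
#'
#' Fits the logistic treatment-initiation models used in the stabilized
#' inverse probability of treatment weights.  All models are fitted on
#' person-period rows with no treatment at the previous visit
#' (\code{A_prev = 0}): once treatment has started it continues with
#' probability 1 (absorbing treatment), so treated-history rows carry no
#' information and never enter any fit.
#' \itemize{
#'   \item denominator: pooled logistic regression of current treatment on
#'     the current confounder value, \code{A ~ L} (the full-confounder-history
#'     model);
#'   \item numerator, marginal stabilization: a separate intercept per visit
#'     (the empirical initiation proportion at each k);
#'   \item numerator, baseline-conditional stabilization: a separate
#'     intercept and baseline-covariate (\code{L0}) slope per visit.
#' }
#' Visits with no at-risk untreated rows are omitted from the per-visit
#' numerator models with a warning.
#'
#' @param pp a \code{person_period} table.
#' @param numerator which numerator models to fit: \code{"marginal"},
#'   \code{"L0"} or \code{"both"}.
#' @return object of class \code{treatment_models}.
#' @export
fit_treatment_models <- function(pp, numerator = c("both", "marginal", "L0")) {
  numerator <- match.arg(numerator)
  atrisk <- pp[pp$A_prev == 0, , drop = FALSE]
  if (nrow(atrisk) == 0) stop("no at-risk (previously untreated) rows")
  den <- stats::glm(A ~ L, family = stats::binomial(), data = atrisk)
  ks <- sort(unique(atrisk$k))
  all_k <- sort(unique(pp$k))
  if (length(setdiff(all_k, ks)) > 0)
    warning("no at-risk untreated rows at visits ",
            paste(setdiff(all_k, ks), collapse = ", "),
            "; numerator models omit them")
  atrisk$fk <- factor(atrisk$k, levels = ks)
  num_marg <- if (numerator %in% c("both", "marginal"))
    stats::glm(A ~ 0 + fk, family = stats::binomial(), data = atrisk) else NULL
  num_l0 <- if (numerator %in% c("both", "L0"))
    stats::glm(A ~ 0 + fk + fk:L0, family = stats::binomial(),
               data = atrisk) else NULL
  if (!den$converged || any(!is.finite(stats::coef(den))))
    stop("treatment denominator model did not converge (separation?)")
  structure(list(denominator = den, numerator_marginal = num_marg,
                 numerator_L0 = num_l0, visits = ks),
            class = "treatment_models")
}

# probability of the *observed* treatment value under a fitted logistic
# model, with flooring to avoid division blow-ups; attr "floored" counts rows
prob_observed <- function(p1, a, floor = 1e-12) {
  p <- ifelse(a == 1, p1, 1 - p1)
  nfl <- sum(p < floor)
  if (nfl > 0) {
    warning("floored ", nfl, " probabilities at ", floor,
            " (positivity concern)")
    p <- pmax(p, floor)
  }
  p
}

# predict from a per-visit-factor numerator model; `visits` are the levels
# the model was fitted with
predict_per_k <- function(fit, visits, k, newdata) {
  if (any(!k %in% visits))
    stop("no numerator model for visits: ",
         paste(setdiff(unique(k), visits), collapse = ", "))
  newdata$fk <- factor(k, levels = visits)
  as.numeric(stats::predict(fit, newdata = newdata, type = "response"))
}

#' Compute stabilized inverse probability of treatment weights
#'
#' The weight on the person-period row at interval k is the cumulative
#' product over visits j = 0..k of the stabilized factor
#' numerator-probability(observed A_j) / denominator-probability(observed
#' A_j).  Factors equal 1 whenever treatment was already ongoing at the
#' previous visit (absorbing treatment: the observed value has probability 1
#' under both models).
#'
#' @param models a \code{treatment_models} object.
#' @param pp the \code{person_period} table the models were fitted on (or a
#'   compatible one, e.g. a bootstrap resample).
#' @param stabilization \code{"conditional_L0"} for numerators conditioning
#'   on the baseline covariate, \code{"marginal"} for per-visit intercepts
#'   only, \code{"none"} for unstabilized weights (numerator 1).
#' @return numeric weight vector aligned with the rows of \code{pp}, of class
#'   \code{weight_series} with attribute \code{kind}.
#' @export
compute_iptw <- function(models, pp,
                         stabilization = c("conditional_L0", "marginal", "none")) {
  stabilization <- match.arg(stabilization)
  p_den1 <- stats::predict(models$denominator, newdata = pp, type = "response")
  num1 <- switch(stabilization,
    conditional_L0 = {
      if (is.null(models$numerator_L0)) stop("no L0 numerator model fitted")
      predict_per_k(models$numerator_L0, models$visits, pp$k, pp)
    },
    marginal = {
      if (is.null(models$numerator_marginal)) stop("no marginal numerator model")
      predict_per_k(models$numerator_marginal, models$visits, pp$k, pp)
    },
    none = ifelse(pp$A == 1, 1, 0) # placeholder; handled below
  )
  fac_den <- prob_observed(p_den1, pp$A)
  fac_num <- if (stabilization == "none") rep(1, nrow(pp))
             else prob_observed(num1, pp$A)
  fac <- fac_num / fac_den
  fac[pp$A_prev == 1] <- 1    # observed value had probability 1
  w <- cumprod_by(fac, pp$id, pp$k)
  weight_series(w, kind = switch(stabilization,
                                 conditional_L0 = "iptw_conditional_L0",
                                 marginal = "iptw", none = "iptw_unstabilized"))
}

# cumulative product of x within groups g, rows ordered by ord within group
cumprod_by <- function(x, g, ord) {
  gi <- match(g, unique(g))
  o <- order(gi, ord)
  lxo <- log(x[o])                       # log-space: a global running
  gio <- gi[o]                           # product would under/overflow
  cs <- cumsum(lxo)
  first <- !duplicated(gio)
  base <- cs[first] - lxo[first]         # running log-sum before group start
  res <- exp(cs - base[gio])
  out <- numeric(length(x))
  out[o] <- res
  out
}

weight_series <- function(w, kind) {
  if (any(!is.finite(w) | w <= 0)) stop("non-positive or non-finite weights")
  structure(w, kind = kind, class = c("weight_series", "numeric"))
}

#' Fit artificial-censoring models on the (uncensored) trial stack
#'
#' Fits the logistic models behind the inverse probability of
#' artificial-censoring weights, pooled across trials, on the at-risk
#' person-visits of the non-initiator arm: individuals still untreated and
#' alive at visit m = trial + j (j >= 1), whose observed treatment at m is
#' the deviation indicator.  The denominator conditions on the current
#' confounder value (\code{A ~ L}); the numerator conditions only on the
#' trial-baseline covariate, with a separate intercept and slope per
#' calendar visit (\code{A ~ L_base} fitted per visit).  Under absorbing
#' treatment the initiator arm cannot deviate, so no models are needed
#' for it.
#'
#' @param trials an *uncensored* trial stack from [build_trials()].
#' @return object of class \code{ipacw_models}.
#' @export
fit_ipacw_models <- function(trials) {
  ar <- trials[trials$arm == 0 & trials$j >= 1 & trials$A_prev == 0, ,
               drop = FALSE]
  if (nrow(ar) == 0) stop("no at-risk non-initiator person-visits")
  ar$visit <- ar$trial + ar$j
  den <- stats::glm(A ~ L, family = stats::binomial(), data = ar)
  vs <- sort(unique(ar$visit))
  ar$fk <- factor(ar$visit, levels = vs)
  num <- stats::glm(A ~ 0 + fk + fk:L_base, family = stats::binomial(),
                    data = ar)
  structure(list(denominator = den, numerator = num, visits = vs),
            class = "ipacw_models")
}

#' Compute stabilized inverse probability of artificial-censoring weights
#'
#' Within each trial, the weight is 1 on the first interval (0 <= t < 1) for
#' both arms, and 1 at all times on the initiator arm under absorbing
#' treatment (initiators cannot deviate).  On the non-initiator arm at
#' interval j >= 1 the weight is the cumulative product over visits
#' m = trial+1 .. trial+j of the stabilized probability of remaining
#' untreated, Pr(A_m = 0 | L_base) / Pr(A_m = 0 | L_m), evaluated on the
#' surviving, non-deviated rows.  Rows removed by artificial censoring
#' receive no weight because they no longer exist.
#'
#' @param models an \code{ipacw_models} object fitted on the uncensored stack.
#' @param trials an artificially censored trial stack
#'   (from [apply_artificial_censoring()]).
#' @return weight vector aligned with the rows of \code{trials}, class
#'   \code{weight_series}.
#' @export
compute_ipacw <- function(models, trials) {
  w <- rep(1, nrow(trials))
  sel <- trials$arm == 0 & trials$j >= 1
  if (any(sel)) {
    tr <- trials[sel, , drop = FALSE]
    tr$visit <- tr$trial + tr$j
    p_den1 <- stats::predict(models$denominator, newdata = tr, type = "response")
    p_num1 <- predict_per_k(models$numerator, models$visits, tr$visit, tr)
    # observed treatment on retained non-initiator rows is 0 by construction
    zero <- rep(0L, nrow(tr))
    fac <- prob_observed(p_num1, zero) / prob_observed(p_den1, zero)
    key <- paste(tr$id, tr$trial, sep = "\r")
    w[sel] <- cumprod_by(fac, key, tr$j)
  }
  weight_series(w, kind = "ipacw")
}

#' Inverse probability of censoring weights for loss to follow-up
#'
#' Generic hook for ordinary dropout (loss to follow-up, as distinct from
#' administrative censoring and from artificial censoring).  When the
#' person-period table has no dropout indicator column, or no dropout
#' events, all weights are 1.  Otherwise the weight is the cumulative
#' product of stabilized inverse probabilities of remaining uncensored,
#' following the same template as the treatment weights.
#'
#' @param censor_models \code{NULL}, or a list with fitted binomial models
#'   \code{denominator} (dropout on current covariates) and optional
#'   \code{numerator} (dropout on baseline covariates); both are evaluated
#'   per row with \code{predict(type = "response")}.
#' @param pp a \code{person_period} table, optionally with a 0/1 column
#'   \code{dropout} marking the interval in which loss to follow-up occurred.
#' @return weight vector of class \code{weight_series}.
#' @export
compute_ipcw <- function(censor_models = NULL, pp) {
  if (is.null(pp$dropout) || all(pp$dropout == 0) || is.null(censor_models))
    return(weight_series(rep(1, nrow(pp)), kind = "ipcw"))
  p_den <- stats::predict(censor_models$denominator, newdata = pp,
                          type = "response")
  p_num <- if (is.null(censor_models$numerator)) rep(NA_real_, nrow(pp))
           else stats::predict(censor_models$numerator, newdata = pp,
                               type = "response")
  # probability of remaining uncensored through each interval; the dropout
  # interval itself gets no further rows, so factors use uncensored rows only
  fac_den <- prob_observed(1 - p_den, 1)
  fac_num <- if (anyNA(p_num)) rep(1, nrow(pp)) else prob_observed(1 - p_num, 1)
  w <- cumprod_by(fac_num / fac_den, pp$id, pp$k)
  weight_series(w, kind = "ipcw")
}

#' Truncate weights at a pooled percentile
#'
#' Values above the given percentile of the pooled weight distribution (all
#' person-period rows together) are set to that percentile; other values are
#' unchanged.  The percentile is the inverse-CDF (type-1) empirical
#' quantile, which makes truncation idempotent: re-truncating the capped
#' distribution at the same percentile changes nothing.
#'
#' @param w a \code{weight_series} (or numeric vector).
#' @param percentile percentile in (0, 100].
#' @return truncated \code{weight_series}; attribute \code{n_truncated}
#'   counts modified rows.
#' @export
truncate_weights <- function(w, percentile = 95) {
  if (length(w) == 0) stop("empty weight vector")
  if (percentile <= 0 || percentile > 100) stop("percentile must be in (0,100]")
  cap <- stats::quantile(as.numeric(w), percentile / 100, names = FALSE, type = 1)
  out <- pmin(as.numeric(w), cap)
  structure(out, kind = "truncated", n_truncated = sum(w > cap),
            class = c("weight_series", "numeric"))
}

#' Summarize the largest weight by time period
#'
#' Diagnostic surface for comparing weight extremity across approaches: the
#' maximum weight within each unit time period (for sequential trials, time
#' since the start of the trial).
#'
#' @param w weight vector.
#' @param period integer period index per row (person-period \code{k}, or
#'   trial-time \code{j}).
#' @return data.frame with columns \code{period}, \code{max_weight}.
#' @export
max_weight_by_period <- function(w, period) {
  agg <- tapply(as.numeric(w), period, max)
  data.frame(period = as.integer(names(agg)), max_weight = as.numeric(agg),
             row.names = NULL)
}
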