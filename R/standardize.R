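# --- regime treatment paths -------------------------------------------------

# Per-event-time treatment contribution increments for an Aalen fit under a
# deterministic regime: at an event time in interval [m, m+1) the treatment
# part of the hazard is
#   lags:     sum_{j=0..m} a(m-j) dB_lagj(t)
#   current:  a(m) dB_A(t)
#   duration: (sum_{k<=m} a(k)) dB_dur(t)
#   arm:      a(0) dB_arm(t)   (constant-arm sequential-trials design)
aalen_treatment_increments <- function(fit, regime) {
  des <- fit$design
  m <- ceiling(fit$times) - 1
  a_at <- function(k) {
    k <- pmin(pmax(k, 0), regime$K - 1)
    regime$a[k + 1L]
  }
  switch(des$treatment,
    none = numeric(length(fit$times)),
    arm = regime$a[1L] * fit$dB[, "arm"],
    current = a_at(m) * fit$dB[, "A"],
    duration = vapply(seq_along(m), function(r)
      sum(regime$a[seq_len(m[r] + 1L)]), numeric(1)) * fit$dB[, "A_dur"],
    lags = {
      cols <- c("A", paste0("A_lag", seq_len(des$n_lags)))
      out <- numeric(length(fit$times))
      for (j in 0:des$n_lags) {
        active <- m >= j
        out[active] <- out[active] +
          a_at(m[active] - j) * fit$dB[active, cols[j + 1L]]
      }
      out
    })
}

# cumulative hazard contributions shared by all members of a population:
# intercept + treatment-under-regime, evaluated at `times`
aalen_base_cumhaz <- function(fit, regime, times) {
  dH <- fit$dB[, "(Intercept)"] + aalen_treatment_increments(fit, regime)
  H <- cumsum(dH)
  c(0, H)[findInterval(times, fit$times) + 1L]
}

# Cox analogue: G_a(t) = sum_{s<=t} exp(g(a; beta)) dH0(s), where under the
# supported designs g is constant within visit intervals
cox_base_cumhaz <- function(fit, regime, times) {
  base <- if (fit$stratified) fit$baseline[["0"]] else fit$baseline
  des <- fit$design
  m <- ceiling(base$times) - 1
  g <- switch(des$treatment,
    none = rep(0, length(base$times)),
    arm = regime$a[1L] * fit$coef[["arm"]],
    current = regime$a[pmin(m, regime$K - 1) + 1L] * fit$coef[["A"]],
    duration = vapply(m, function(mm)
      sum(regime$a[seq_len(min(mm, regime$K - 1) + 1L)]),
      numeric(1)) * fit$coef[["A_dur"]],
    stop("unsupported Cox treatment design"))
  G <- cumsum(exp(g) * base$dH0)
  c(0, G)[findInterval(times, base$times) + 1L]
}

# linear predictor of the covariate part for each member of `pop`
covariate_lp <- function(fit, pop, times = NULL) {
  covs <- fit$design$covariates
  if (length(covs) == 0) return(NULL)
  miss <- setdiff(covs, names(pop))
  if (length(miss) > 0)
    stop("standardization population lacks covariates: ",
         paste(miss, collapse = ", "))
  as.matrix(pop[covs])
}

# --- survival curves --------------------------------------------------------

survival_curve <- function(times, S, regime, population, n_clamped = 0L) {
  structure(data.frame(t = times, S = S),
            regime = regime, population = population, n_clamped = n_clamped,
            class = c("survival_curve", "data.frame"))
}

#' Counterfactual survival under a deterministic regime
#'
#' Evaluates the fitted MSM's survival function under a treatment regime,
#' for one covariate record (when the MSM conditions on covariates) or
#' marginally (when it does not).  For the additive model,
#' S(tau) = exp(-[cumulative intercept + regime treatment terms + covariate
#' terms]) evaluated exactly on the event-time step function; for the Cox
#' model the Breslow baseline increments are scaled by exp(linear predictor)
#' interval by interval.  The final survival probability is clamped to
#' [0, 1] (negative fitted additive increments are retained inside the
#' cumulative, never clipped, because clipping increments would bias the
#' cumulative coefficients); the number of clamped values is recorded.
#'
#' @param fit an \code{aalen_msm} or \code{cox_msm}.
#' @param regime a [regime_spec()].
#' @param newdata a one-row data.frame of covariate values, required iff the
#'   fit conditions on covariates.
#' @param times evaluation grid (default: the fit's event times).
#' @return a \code{survival_curve} data.frame with columns \code{t, S}.
#' @export
survival_under_regime <- function(fit, regime, newdata = NULL, times = NULL) {
  covs <- fit$design$covariates
  if (length(covs) > 0 && is.null(newdata))
    stop("fit conditions on covariates (", paste(covs, collapse = ", "),
         "); supply `newdata` or use standardize_marginal()")
  if (length(covs) > 0 && nrow(newdata) != 1)
    stop("`newdata` must have exactly one row")
  if (inherits(fit, "aalen_msm")) {
    if (is.null(times)) times <- fit$times
    H <- aalen_base_cumhaz(fit, regime, times)
    if (length(covs) > 0) {
      cumB <- cum_coef_at(fit, times)[, covs, drop = FALSE]
      H <- H + drop(cumB %*% as.numeric(newdata[1, covs]))
    }
  } else if (inherits(fit, "cox_msm")) {
    base <- if (fit$stratified) fit$baseline[["0"]] else fit$baseline
    if (is.null(times)) times <- base$times
    G <- cox_base_cumhaz(fit, regime, times)
    lp <- if (length(covs) > 0)
      sum(fit$coef[covs] * as.numeric(newdata[1, covs])) else 0
    H <- exp(lp) * G
  } else stop("unsupported fit class")
  S <- exp(-H)
  ncl <- sum(S > 1)
  survival_curve(times, pmin(S, 1), regime,
                 population = if (length(covs) > 0) "conditional" else "marginal",
                 n_clamped = ncl)
}

#' Standardize conditional survival to a reference population (cloning)
#'
#' Empirical standardization: each member of the reference population is
#' cloned under the regime (treatment history set to the regime, covariates
#' kept at the member's values), the conditional survival curve is computed
#' for each clone from the fitted MSM, and the curves are averaged.  For
#' simulation use, the default reference population is the full sample's
#' baseline covariate at k = 0; for the sequential-trials MSM the clone's
#' trial-baseline covariate is set to the member's baseline value, so both
#' approaches standardize to the same time-zero population.  Covariate
#' values outside the range seen in fitting trigger an extrapolation
#' warning.
#'
#' @param fit an \code{aalen_msm} or \code{cox_msm} conditioning on
#'   covariates.
#' @param regime a [regime_spec()].
#' @param pop data.frame: one row per reference-population member with the
#'   fit's covariate columns.
#' @param times evaluation grid (default: the fit's event times).
#' @param check_support warn when pop covariates fall outside the fitted
#'   range (default off; range information is not retained by default).
#' @return a \code{survival_curve} with population \code{"standardized"}.
#' @export
standardize_marginal <- function(fit, regime, pop, times = NULL,
                                 check_support = FALSE) {
  covs <- fit$design$covariates
  if (length(covs) == 0)
    stop("fit has no covariate conditioning; use survival_under_regime()")
  lpmat <- covariate_lp(fit, pop)    # n_C x n_cov
  if (inherits(fit, "aalen_msm")) {
    if (is.null(times)) times <- fit$times
    Hbase <- aalen_base_cumhaz(fit, regime, times)
    cumB <- cum_coef_at(fit, times)[, covs, drop = FALSE]  # n_t x n_cov
    Hcov <- lpmat %*% t(cumB)                              # n_C x n_t
    S <- colMeans(pmin(exp(-outer(rep(1, nrow(pop)), Hbase) - Hcov), 1))
  } else if (inherits(fit, "cox_msm")) {
    base <- if (fit$stratified) fit$baseline[["0"]] else fit$baseline
    if (is.null(times)) times <- base$times
    G <- cox_base_cumhaz(fit, regime, times)
    lp <- drop(lpmat %*% fit$coef[covs])
    S <- colMeans(exp(-outer(exp(lp), G)))
  } else stop("unsupported fit class")
  survival_curve(times, S, regime, population = "standardized")
}

#' Marginal risk difference between two regimes
#'
#' RD(tau) = S1(tau) - S0(tau): survival under the "always treated" regime
#' minus survival under the "never treated" regime, so a positive value
#' means better survival when always treated.  Curves are evaluated by
#' step-function lookup at each horizon and must refer to the same
#' population.
#'
#' @param s1,s0 \code{survival_curve}s under the two regimes.
#' @param taus horizons at which to evaluate the risk difference.
#' @return a \code{rd_curve} data.frame with columns \code{t, S1, S0, RD}.
#' @export
risk_difference <- function(s1, s0, taus = NULL) {
  if (!identical(attr(s1, "population"), attr(s0, "population")))
    stop("survival curves refer to different populations")
  if (is.null(taus)) taus <- sort(unique(c(s1$t, s0$t)))
  v1 <- curve_at(s1, taus)
  v0 <- curve_at(s0, taus)
  structure(data.frame(t = taus, S1 = v1, S0 = v0, RD = v1 - v0),
            population = attr(s1, "population"),
            class = c("rd_curve", "data.frame"))
}

#' Evaluate a survival curve at given times
#'
#' Step-function lookup with S(t) = 1 before the first stored time.
#'
#' @param curve a \code{survival_curve}.
#' @param taus times.
#' @return numeric vector.
#' @export
curve_at <- function(curve, taus) {
  c(1, curve$S)[findInterval(taus, curve$t) + 1L]
}
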