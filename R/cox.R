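#' Fit a weighted Cox proportional-hazards MSM
#'
#' Coefficients maximize the weighted partial likelihood on (tstart, tstop]
#' counting-process rows (Efron correction for ties; continuous simulated
#' event times make ties a measure-zero event, so the choice matters only
#' for user data).  The cumulative baseline hazard is the weighted Breslow
#' estimator evaluated at the covariate origin (all design columns zero),
#' not at covariate means.  For the sequential-trials analysis the baseline
#' hazard is common across trials by default; \code{stratify_trial = TRUE}
#' allows a separate baseline per trial, in which case marginal-risk
#' computation should use the trial-0 baseline (the only one observed over
#' the full horizon).
#'
#' @inheritParams fit_aalen_msm
#' @param stratify_trial stratify the baseline hazard by the \code{trial}
#'   column (trial stacks only).
#' @return object of class \code{cox_msm}: coefficient vector \code{coef},
#'   its \code{vcov}, the Breslow baseline (\code{times}, \code{dH0},
#'   \code{H0}; a list per stratum when stratified), the design, and the
#'   underlying \code{coxph} fit.
#' @export
fit_cox_msm <- function(data, design, weights = NULL, stratify_trial = FALSE) {
  if (is.null(weights)) weights <- rep(1, nrow(data))
  dm <- design_matrix(design, data)
  cols <- setdiff(colnames(dm$X), "(Intercept)")
  if (any(is.finite(dm$activation)))
    stop("the interval-dependent lag design is additive-hazards only; ",
         "use treatment = 'current', 'duration' or 'arm' for Cox MSMs")
  df <- data.frame(tstart = data$tstart, tstop = data$tstop, Y = data$Y,
                   check.names = FALSE)
  for (cl in cols) df[[cl]] <- dm$X[, cl]
  df$.w <- as.numeric(weights)
  rhs <- if (length(cols) > 0) paste(sprintf("`%s`", cols), collapse = " + ")
         else "1"
  if (stratify_trial) {
    if (is.null(data$trial)) stop("stratify_trial requires a `trial` column")
    df$trial <- data$trial
    rhs <- paste(rhs, "+ strata(trial)")
  }
  fml <- stats::as.formula(paste("survival::Surv(tstart, tstop, Y) ~", rhs))
  fit <- survival::coxph(fml, data = df, weights = .w, ties = "efron",
                         robust = FALSE, x = FALSE, model = FALSE)
  if (length(cols) > 0 && any(is.na(stats::coef(fit))))
    stop("singular information in Cox MSM: ",
         paste(cols[is.na(stats::coef(fit))], collapse = ", "))
  beta <- if (length(cols) > 0) stats::coef(fit) else numeric(0)
  names(beta) <- cols
  lp <- if (length(cols) > 0) drop(dm$X[, cols, drop = FALSE] %*% beta) else
    rep(0, nrow(df))
  strat <- if (stratify_trial) df$trial else rep(0L, nrow(df))
  base <- lapply(sort(unique(strat)), function(s) {
    i <- strat == s
    breslow_baseline(df$tstart[i], df$tstop[i], df$Y[i], df$.w[i], lp[i])
  })
  names(base) <- as.character(sort(unique(strat)))
  structure(list(coef = beta,
                 vcov = if (length(cols) > 0) stats::vcov(fit) else NULL,
                 baseline = if (stratify_trial) base else base[[1L]],
                 stratified = stratify_trial, design = design,
                 coxph = fit),
            class = "cox_msm")
}

# Weighted Breslow cumulative baseline hazard on start-stop data:
# dH0(t) = sum_{events at t} w / sum_{at risk at t} w exp(lp)
breslow_baseline <- function(tstart, tstop, ev, w, lp) {
  et <- sort(unique(tstop[ev == 1]))
  r <- w * exp(lp)
  n <- length(r)
  oA <- order(tstop, decreasing = TRUE)
  csA <- cumsum(r[oA])
  oB <- order(tstart, decreasing = TRUE)
  csB <- cumsum(r[oB])
  nA <- n - findInterval(et, sort(tstop), left.open = TRUE)
  nB <- n - findInterval(et, sort(tstart), left.open = TRUE)
  denom <- csA[nA] - ifelse(nB > 0, csB[pmax(nB, 1L)], 0)
  num <- rowsum(w[ev == 1], group = tstop[ev == 1])
  num <- num[match(et, sort(unique(tstop[ev == 1]))), 1L]
  dH0 <- unname(num / denom)
  list(times = et, dH0 = dH0, H0 = cumsum(dH0))
}

#' Wald test for a common treatment effect across trials
#'
#' Adds trial-by-arm interaction terms to the sequential-trials Cox MSM and
#' performs a Wald test of their joint nullity.  Rejection indicates that
#' the effect of treatment initiation on the hazard depends on the visit at
#' which treatment was initiated, in which case a pooled common-effect
#' analysis is questionable.  Inestimable interaction terms (e.g. a
#' trial-arm cell with no events) are dropped with a warning and the
#' degrees of freedom reduced.
#'
#' @param trials an artificially censored \code{trial_stack}.
#' @param weights row weights (IPACW).
#' @param covariates covariate column names for the MSM (default trial-
#'   baseline covariate).
#' @return list with \code{statistic}, \code{df}, \code{p_value}.
#' @export
test_common_treatment_effect <- function(trials, weights = NULL,
                                         covariates = "L_base") {
  if (length(unique(trials$trial)) < 2) stop("need at least 2 trials")
  if (is.null(weights)) weights <- rep(1, nrow(trials))
  df <- as.data.frame(trials)
  df$.w <- as.numeric(weights)
  df$ftrial <- factor(df$trial)
  rhs <- paste(c("arm", "ftrial", "arm:ftrial", covariates), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(tstart, tstop, Y) ~", rhs))
  fit <- survival::coxph(fml, data = df, weights = .w, ties = "efron",
                         robust = FALSE)
  b <- stats::coef(fit)
  inter <- grep("^arm:ftrial", names(b))
  drop <- inter[is.na(b[inter])]
  if (length(drop) > 0) {
    warning("dropping inestimable interaction terms: ",
            paste(names(b)[drop], collapse = ", "))
    inter <- setdiff(inter, drop)
  }
  if (length(inter) == 0) stop("no estimable trial-by-arm interactions")
  bi <- b[inter]
  Vi <- stats::vcov(fit)[inter, inter, drop = FALSE]
  stat <- drop(t(bi) %*% solve(Vi, bi))
  list(statistic = stat, df = length(inter),
       p_value = stats::pchisq(stat, df = length(inter), lower.tail = FALSE))
}
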