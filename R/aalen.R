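#' Specify the hazard-model design of an MSM
#'
#' The treatment part of the marginal structural model can be one of:
#' \describe{
#'   \item{\code{"lags"}}{a separate (time-varying, for the additive model)
#'     coefficient for treatment at each lag: at event times in interval
#'     \code{[m, m+1)} the design contains treatment at visits m, m-1, ..., 0.
#'     This is the correct treatment-history form for the MSM-IPTW analysis
#'     when the data-generating hazard is additive in current treatment and
#'     the confounder feeds back on treatment.  Lag-j columns enter the
#'     design only at event times with \code{floor(t) >= j} (earlier they
#'     are identically zero and would make the normal equations singular).}
#'   \item{\code{"current"}}{treatment status entering the current interval
#'     only.}
#'   \item{\code{"duration"}}{cumulative number of treated visits.}
#'   \item{\code{"arm"}}{the constant trial-arm indicator; the only option
#'     for the sequential-trials MSM because after artificial censoring all
#'     follow-up is under sustained treatment or sustained non-treatment.}
#'   \item{\code{"none"}}{no treatment terms (intercept-only baseline,
#'     giving the Nelson-Aalen estimator when no covariates are added).}
#' }
#' Baseline-conditioning covariates are named columns of the fitting data
#' (e.g. \code{"L0"} for the MSM conditional on the covariate at time zero,
#' or \code{"L_base"} for the trial-baseline covariate).
#'
#' @param treatment treatment term type (see above).
#' @param covariates character vector of covariate column names.
#' @param n_lags for \code{"lags"}: number of lag columns beyond lag 0.
#' @return object of class \code{msm_design}.
#' @export
msm_design <- function(treatment = c("lags", "current", "arm", "duration", "none"),
                       covariates = character(), n_lags = 4L) {
  treatment <- match.arg(treatment)
  structure(list(treatment = treatment, covariates = covariates,
                 n_lags = as.integer(n_lags)),
            class = "msm_design")
}

# Build the design matrix and per-column activation times.
# Column j is in the risk-set design only at event times t with
# ceiling(t) - 1 >= activation[j].
design_matrix <- function(design, data) {
  tcols <- switch(design$treatment,
    none = character(),
    current = "A",
    arm = "arm",
    duration = "A_dur",
    lags = c("A", paste0("A_lag", seq_len(design$n_lags))))
  act <- switch(design$treatment,
    lags = 0:design$n_lags,
    rep(-Inf, length(tcols)))
  if (design$treatment == "duration" && is.null(data$A_dur)) {
    lagc <- grep("^A_lag", names(data), value = TRUE)
    data$A_dur <- data$A + if (length(lagc) > 0)
      rowSums(as.matrix(data[lagc])) else 0
  }
  miss <- setdiff(c(tcols, design$covariates), names(data))
  if (length(miss) > 0)
    stop("design columns absent from data: ", paste(miss, collapse = ", "))
  cols <- c(tcols, design$covariates)
  X <- cbind(`(Intercept)` = rep(1, nrow(data)),
             as.matrix(data[cols]))
  list(X = X, activation = c(-Inf, act, rep(-Inf, length(design$covariates))),
       treatment_cols = tcols)
}

#' Fit a weighted Aalen additive-hazards MSM
#'
#' At each event time t the increment of the cumulative coefficient vector
#' solves the weighted least-squares normal equations over the at-risk rows
#' (\code{tstart < t <= tstop}): dB(t) = (X'WX)^{-1} X'W dN(t).  The
#' cumulative coefficients B(t) are piecewise constant with jumps at event
#' times and B(0) = 0.  Rows carry multiplicative weights (IPTW, IPACW, or
#' their truncated versions); the fit is invariant to rescaling all weights
#' by a constant.  Singular increments (rank-deficient weighted design at an
#' event time) are skipped with the cumulative carried forward and counted
#' in the diagnostics, or raise an error in strict mode.
#'
#' @param data a \code{person_period} table or \code{trial_stack} with
#'   columns \code{tstart}, \code{tstop}, \code{Y} and the design columns.
#' @param design an [msm_design()].
#' @param weights row weights (default all 1).
#' @param singular how to handle singular increments: \code{"skip"} or
#'   \code{"error"}.
#' @return object of class \code{aalen_msm}: event \code{times}, increment
#'   matrix \code{dB}, cumulative coefficients \code{B} (one row per event
#'   time, one column per term), the design, and diagnostics.
#' @export
fit_aalen_msm <- function(data, design, weights = NULL,
                          singular = c("skip", "error")) {
  singular <- match.arg(singular)
  if (is.null(weights)) weights <- rep(1, nrow(data))
  stopifnot(length(weights) == nrow(data), all(weights > 0))
  dm <- design_matrix(design, data)
  fit <- aalen_core(dm$X, as.numeric(weights), data$tstart, data$tstop,
                    data$Y, dm$activation, singular = singular)
  fit$design <- design
  fit$activation <- dm$activation
  class(fit) <- "aalen_msm"
  fit
}

# Weighted Aalen least-squares increments over start-stop data.
# Risk-set cross-product matrices are obtained from two reverse cumulative
# sums: M(t) = sum_{tstop >= t} w x x' - sum_{tstart >= t} w x x'
# (the second set is contained in the first since tstop > tstart).
aalen_core <- function(X, w, tstart, tstop, ev, activation,
                       singular = "skip") {
  n <- nrow(X); p <- ncol(X)
  et <- sort(unique(tstop[ev == 1]))
  ne <- length(et)
  if (ne == 0) stop("no events in the data")
  pair_i <- rep(seq_len(p), times = p:1)
  pair_j <- unlist(lapply(seq_len(p), function(i) i:p))
  Z <- X[, pair_i, drop = FALSE] * X[, pair_j, drop = FALSE] * w
  oA <- order(tstop, decreasing = TRUE)
  csA <- apply(Z[oA, , drop = FALSE], 2, cumsum)
  oB <- order(tstart, decreasing = TRUE)
  csB <- apply(Z[oB, , drop = FALSE], 2, cumsum)
  sstop <- sort(tstop); sstart <- sort(tstart)
  nA <- n - findInterval(et, sstop, left.open = TRUE)   # #{tstop >= t}
  nB <- n - findInterval(et, sstart, left.open = TRUE)  # #{tstart >= t}
  evr <- which(ev == 1)
  rhs_all <- rowsum(X[evr, , drop = FALSE] * w[evr], group = tstop[evr])
  rhs_all <- rhs_all[match(et, sort(unique(tstop[evr]))), , drop = FALSE]
  m_int <- ceiling(et) - 1   # interval index of each event time
  dB <- matrix(0, ne, p, dimnames = list(NULL, colnames(X)))
  M <- matrix(0, p, p)
  ui <- cbind(pair_i, pair_j); li <- cbind(pair_j, pair_i)
  skipped <- 0L
  # fast path: plain solves (no per-event condition handling); on any
  # singular increment, redo the loop with per-event error capture
  solve_all <- function(capture) {
    for (r in seq_len(ne)) {
      v <- csA[nA[r], ]
      if (nB[r] > 0) v <- v - csB[nB[r], ]
      M[ui] <- v; M[li] <- v
      a <- which(activation <= m_int[r])
      inc <- if (capture)
        tryCatch(solve(M[a, a, drop = FALSE], rhs_all[r, a]),
                 error = function(e) NULL)
      else solve(M[a, a, drop = FALSE], rhs_all[r, a])
      if (is.null(inc)) {
        if (singular == "error")
          stop("singular weighted design at event time ", et[r])
        skipped <<- skipped + 1L
      } else dB[r, a] <- inc
    }
    dB
  }
  dB <- tryCatch(solve_all(capture = FALSE),
                 error = function(e) solve_all(capture = TRUE))
  B <- apply(dB, 2, cumsum)
  if (ne == 1) B <- matrix(B, 1, p, dimnames = list(NULL, colnames(X)))
  list(times = et, dB = dB, B = B, terms = colnames(X),
       n_events = ne, n_skipped = skipped)
}

#' Evaluate cumulative coefficients at given times
#'
#' Step-function lookup of the cumulative coefficient matrix B(t) (zero
#' before the first event time).
#'
#' @param fit an \code{aalen_msm}.
#' @param times evaluation times.
#' @return matrix \code{length(times) x n_terms}.
#' @export
cum_coef_at <- function(fit, times) {
  idx <- findInterval(times, fit$times)
  B0 <- rbind(0, fit$B)
  out <- B0[idx + 1L, , drop = FALSE]
  dimnames(out) <- list(NULL, fit$terms)
  out
}

#' @export
print.aalen_msm <- function(x, ...) {
  cat("Weighted Aalen additive-hazards MSM\n")
  cat("  terms:", paste(x$terms, collapse = ", "), "\n")
  cat("  event times:", x$n_events,
      if (x$n_skipped > 0) paste0("(", x$n_skipped, " singular increments skipped)"),
      "\n")
  cat("  cumulative coefficients at final time:\n")
  print(x$B[nrow(x$B), ])
  invisible(x)
}
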