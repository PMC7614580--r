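#' Scenario parameters for the longitudinal data-generating mechanism
#'
#' The generator draws, per individual, a latent frailty U ~ N(0, u_var),
#' then sequentially over visits k = 0..K-1:
#' \itemize{
#'   \item covariate: L0 ~ N(U, 1); for k >= 1,
#'     Lk ~ N(delta0 + deltaL L_{k-1} + deltaA A_{k-1} + deltaT k + U, 1);
#'   \item treatment: logit Pr(Ak = 1 | A_{k-1} = 0, Lk) = gamma0 + gammaL Lk,
#'     with treatment absorbing (Pr(Ak = 1 | A_{k-1} = 1) = 1);
#'   \item event-time competition on [k, k+1) under the conditional additive
#'     hazard h = alpha0 + alphaA Ak + alphaL Lk + alphaU U, constant within
#'     the interval (piecewise exponential); administrative censoring at K.
#' }
#' The frailty dispersion 0.1 is interpreted as a variance (sd = sqrt(0.1));
#' this interpretation is pinned down by a calibration test against the
#' scenario-1 event fraction.  The treatment-initiation coefficient on the
#' previous treatment value is never needed numerically because treatment is
#' absorbing: the logistic model is only evaluated when A_{k-1} = 0.
#'
#' Presets: scenario 1 has moderate confounding (gammaL = 0.5) and common
#' treatment initiation (25\% treated at the first visit); scenario 2 makes
#' initiation rare (gamma0 = -3, about 5\% treated at the first visit);
#' scenario 3 has strong confounding (gammaL = 3).
#'
#' @param scenario preset name \code{"scenario1"}, \code{"scenario2"},
#'   \code{"scenario3"}, or \code{NULL} for scenario-1 defaults.
#' @param ... overrides of individual parameters.
#' @return object of class \code{scenario_params} (named list).
#' @export
scenario_params <- function(scenario = NULL, ...) {
  p <- list(delta0 = 0, deltaL = 0.8, deltaA = -1, deltaT = 0.1,
            gamma0 = -1, gammaL = 0.5,
            alpha0 = 0.2, alphaA = -0.04, alphaL = 0.015, alphaU = 0.015,
            u_var = 0.1, K = 5L, admin_censor_time = 5,
            treatment_absorbing = TRUE)
  if (!is.null(scenario)) {
    scenario <- match.arg(scenario, c("scenario1", "scenario2", "scenario3"))
    if (scenario == "scenario2") p$gamma0 <- -3
    if (scenario == "scenario3") p$gammaL <- 3
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) stop("unknown parameters: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  num <- unlist(p[setdiff(names(p), "treatment_absorbing")])
  if (any(!is.finite(num))) stop("non-finite scenario parameter")
  if (p$K < 1 || p$admin_censor_time <= 0) stop("invalid K or admin_censor_time")
  structure(p, class = "scenario_params")
}

#' Simulate a longitudinal observational cohort
#'
#' Generates n individuals under the mechanism described in
#' [scenario_params()].  The frailty U is retained in a truth-only column;
#' estimators must never use it.  Covariate and treatment values at visits
#' after the event are set to NA.
#'
#' @param params a \code{scenario_params} object.
#' @param n number of individuals.
#' @param seed integer seed (optional; the caller may also seed globally).
#' @return a \code{longitudinal_cohort} with a \code{U} column.
#' @export
simulate_cohort <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "scenario_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- params$K
  U <- stats::rnorm(n, 0, sqrt(params$u_var))
  L <- matrix(NA_real_, n, K)
  A <- matrix(NA_integer_, n, K)
  for (k in 0:(K - 1)) {
    j <- k + 1L
    mu <- if (k == 0) U else
      params$delta0 + params$deltaL * L[, j - 1L] +
        params$deltaA * A[, j - 1L] + params$deltaT * k + U
    L[, j] <- stats::rnorm(n, mu, 1)
    p_init <- stats::plogis(params$gamma0 + params$gammaL * L[, j])
    newA <- as.integer(stats::runif(n) < p_init)
    A[, j] <- if (k == 0) newA else pmax(A[, j - 1L], newA)  # absorbing
  }
  haz <- pmax(params$alpha0 + params$alphaA * A + params$alphaL * L +
                params$alphaU * U, 0)
  tim <- piecewise_exp_time(haz, stats::rexp(n))
  cens <- is.na(tim) | tim > params$admin_censor_time
  tim[cens] <- params$admin_censor_time
  nv <- pmin(ceiling(tim), K)      # visits survived to
  mask <- outer(nv, 1:K, `<`)      # visit j+1 unseen if nv <= j
  L[mask] <- NA_real_
  A[mask] <- NA_integer_
  out <- data.frame(id = seq_len(n))
  for (k in 0:(K - 1)) out[[paste0("A", k)]] <- A[, k + 1L]
  for (k in 0:(K - 1)) out[[paste0("L", k)]] <- L[, k + 1L]
  out$U <- U
  out$time <- tim
  out$event <- as.integer(!cens)
  longitudinal_cohort(out, K = K, admin_censor_time = params$admin_censor_time)
}

# Invert the piecewise-exponential survivor function.  haz: n x K matrix of
# nonnegative per-unit-interval rates; e: n standard-exponential draws.
# Returns the crossing time, or NA if the total cumulative hazard is not
# reached before the horizon K.
piecewise_exp_time <- function(haz, e) {
  n <- nrow(haz); K <- ncol(haz)
  cum <- matrix(0, n, K + 1L)
  for (k in seq_len(K)) cum[, k + 1L] <- cum[, k] + haz[, k]
  piece <- rowSums(cum[, 1:K, drop = FALSE] <= e)  # interval index (1-based)
  hit <- e < cum[, K + 1L]
  tim <- rep(NA_real_, n)
  i <- which(hit)
  if (length(i) > 0) {
    pc <- piece[i]
    tim[i] <- (pc - 1) + (e[i] - cum[cbind(i, pc)]) / haz[cbind(i, pc)]
  }
  tim
}

#' Draw an event time from a piecewise-constant hazard
#'
#' Samples from the piecewise-exponential distribution with the given
#' per-unit-interval rates by inversion of the survivor function.  Returns
#' \code{NA} when no event occurs before the horizon.
#'
#' @param hazard_pieces nonnegative rates, one per unit interval
#'   \code{[0,1), [1,2), ...}.
#' @param horizon time horizon; defaults to \code{length(hazard_pieces)}.
#' @param u optional standard-exponential draw (for deterministic use).
#' @return event time in \code{[0, horizon)} or \code{NA}.
#' @export
draw_event_time <- function(hazard_pieces, horizon = length(hazard_pieces),
                            u = NULL) {
  if (any(hazard_pieces < 0)) stop("negative hazard rate")
  stopifnot(horizon <= length(hazard_pieces))
  if (is.null(u)) u <- stats::rexp(1)
  tim <- piecewise_exp_time(matrix(hazard_pieces[seq_len(horizon)], 1L), u)
  if (!is.na(tim) && tim >= horizon) tim <- NA_real_
  tim
}

#' Compute ground-truth counterfactual survival curves
#'
#' Emulates a large randomized controlled trial: generates the frailty and
#' covariate process for N individuals with treatment forced to the "always
#' treated" regime and, with the same frailty, baseline covariate and
#' innovation draws (common random numbers), to the "never treated" regime,
#' then records the event times under the conditional additive hazard.  With
#' no censoring before the horizon the Kaplan-Meier estimate equals the
#' empirical survivor function, which is evaluated exactly at the requested
#' times.
#'
#' @param params a \code{scenario_params} object.
#' @param N number of simulated trial participants (1e6 used for fixtures).
#' @param seed integer seed.
#' @param times evaluation grid (defaults to 1..tau_max plus a fine grid).
#' @return object of class \code{truth_curves}: data.frame with columns
#'   \code{t, S1, S0, RD} and attribute \code{N_truth}.
#' @export
compute_truth <- function(params, N = 1e6, seed = NULL, times = NULL) {
  stopifnot(inherits(params, "scenario_params"), N >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- params$K
  tau <- params$admin_censor_time
  if (is.null(times)) times <- sort(unique(c(seq(0, tau, by = 0.05), 1:tau)))
  U <- stats::rnorm(N, 0, sqrt(params$u_var))
  eps <- matrix(stats::rnorm(N * K), N, K)
  e <- stats::rexp(N)
  sim_arm <- function(a) {
    L <- matrix(NA_real_, N, K)
    L[, 1L] <- U + eps[, 1L]
    for (k in 1:(K - 1))
      L[, k + 1L] <- params$delta0 + params$deltaL * L[, k] +
        params$deltaA * a + params$deltaT * k + U + eps[, k + 1L]
    haz <- pmax(params$alpha0 + params$alphaA * a + params$alphaL * L +
                  params$alphaU * U, 0)
    piecewise_exp_time(haz, e)
  }
  t1 <- sim_arm(1); t0 <- sim_arm(0)
  surv_at <- function(tt, grid) vapply(grid, function(g)
    mean(is.na(tt) | tt > g), numeric(1))
  out <- data.frame(t = times, S1 = surv_at(t1, times), S0 = surv_at(t0, times))
  out$RD <- out$S1 - out$S0
  structure(out, N_truth = N, class = c("truth_curves", "data.frame"))
}

#' Load the cached ground-truth survival fixture
#'
#' Counterfactual survival curves computed once from a simulated randomized
#' trial of one million individuals under the scenario-1 parameters
#' (regenerate with \code{scripts/make_truth_fixture.R}).  The truth is the
#' same for all three scenario presets because the treatment-assignment
#' parameters do not enter the counterfactual world.
#'
#' @return a \code{truth_curves} data.frame.
#' @export
truth_fixture <- function() {
  path <- system.file("extdata", "truth_scenario1.csv", package = "seqtrials",
                      mustWork = TRUE)
  df <- utils::read.csv(path)
  structure(df, N_truth = 1e6, class = c("truth_curves", "data.frame"))
}

#' Evaluate truth curves at given horizons
#'
#' @param truth a \code{truth_curves} object (or a data.frame with the same
#'   columns, e.g. read back from CSV).
#' @param taus horizons; must be contained in the stored grid.
#' @param what one of "RD", "S1", "S0".
#' @return numeric vector of the requested quantity at \code{taus}.
#' @export
truth_at <- function(truth, taus, what = c("RD", "S1", "S0")) {
  what <- match.arg(what)
  i <- match(taus, truth$t)
  if (anyNA(i)) stop("horizon not on the stored truth grid: ",
                     paste(taus[is.na(i)], collapse = ", "))
  truth[[what]][i]
}
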