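#' Expand a cohort to person-period (counting-process) form
#'
#' One row per individual per visit interval survived to.  Row k covers
#' \code{(tstart, tstop] = (k, min(k+1, time)]}; the discrete event indicator
#' \code{Y = I(k < time <= k+1) * event} is 1 on at most the last row of an
#' individual.  Intervals are half-open with an event at an integer time
#' belonging to the interval ending at that time.  Lagged treatment and
#' covariate columns before their first definition (e.g. A at visit -1) are
#' set to 0, consistent with no treatment before the start of follow-up.
#'
#' @param cohort a \code{longitudinal_cohort}.
#' @param n_lags_A number of lagged treatment columns \code{A_lag1..}.
#' @param n_lags_L number of lagged covariate columns \code{L_lag1..}.
#' @param extra_cols names of time-fixed columns to carry over (e.g. "Z").
#' @return a \code{person_period} data.frame with columns \code{id, k,
#'   tstart, tstop, Y, A, A_prev, A_lag*, L, L_lag*, L0} plus extras.
#'   \code{A_prev} is treatment at the previous visit (0 at k = 0), the
#'   at-risk conditioning variable for the treatment-process models.
#' @export
to_person_period <- function(cohort, n_lags_A = NULL, n_lags_L = 0L,
                             extra_cols = character()) {
  K <- n_visits(cohort)
  if (is.null(n_lags_A)) n_lags_A <- K - 1L
  stopifnot(n_lags_A >= 0, n_lags_L >= 0)
  nv <- visits_survived(cohort)          # rows per individual
  idx <- rep.int(seq_len(nrow(cohort)), nv)
  k <- sequence(nv) - 1L
  tstop <- pmin(k + 1, cohort$time[idx])
  A <- treatment_matrix(cohort)
  L <- covariate_matrix(cohort)
  pick <- cbind(idx, k + 1L)
  pp <- data.frame(
    id = cohort$id[idx],
    k = k,
    tstart = as.numeric(k),
    tstop = tstop,
    Y = as.integer(cohort$event[idx] == 1 & k == nv[idx] - 1L),
    A = A[pick],
    L = L[pick])
  lagval <- function(mat, lag) {
    v <- numeric(length(k))
    ok <- k - lag >= 0L
    v[ok] <- mat[cbind(idx[ok], k[ok] - lag + 1L)]
    v
  }
  pp$A_prev <- lagval(A, 1L)
  if (n_lags_A > 0) for (j in seq_len(n_lags_A))
    pp[[paste0("A_lag", j)]] <- lagval(A, j)
  if (n_lags_L > 0) for (j in seq_len(n_lags_L))
    pp[[paste0("L_lag", j)]] <- lagval(L, j)
  pp$L0 <- L[idx, 1L]
  for (cl in extra_cols) pp[[cl]] <- cohort[[cl]][idx]
  if (any(pp$tstart >= pp$tstop))
    stop("degenerate person-period rows (tstart >= tstop); check event times")
  class(pp) <- c("person_period", "data.frame")
  pp
}

#' Re-aggregate a person-period table to per-individual follow-up
#'
#' Inverse of the bookkeeping in [to_person_period()]: recovers each
#' individual's total follow-up time and event indicator.  Used to verify
#' that expansion conserves follow-up time and events.
#'
#' @param pp a \code{person_period} table.
#' @return data.frame with columns \code{id}, \code{time}, \code{event}.
#' @export
aggregate_person_period <- function(pp) {
  o <- order(match(pp$id, unique(pp$id)), pp$k)
  pp <- pp[o, ]
  last <- !duplicated(pp$id, fromLast = TRUE)
  data.frame(id = pp$id[last], time = pp$tstop[last],
             event = pp$Y[last])
}
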