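#' Construct a longitudinal cohort object
#'
#' A longitudinal cohort holds one record per individual from a study with
#' regular visits at times k = 0, 1, ..., K-1: binary treatment status
#' \code{A0..A{K-1}}, a real-valued time-dependent covariate \code{L0..L{K-1}},
#' optional time-fixed covariates, a continuous event-or-censoring time
#' \code{time} and an \code{event} indicator.  Treatment and covariate values
#' are recorded at the visits an individual survives to (visit k requires
#' \code{time > k}); later visit columns are \code{NA}.  Variables are assumed
#' constant between visits.
#'
#' @param data data.frame with columns \code{id}, \code{A0..A{K-1}},
#'   \code{L0..L{K-1}}, \code{time}, \code{event}, optionally time-fixed
#'   covariates and a latent frailty column \code{U} (kept only for
#'   truth computation by the simulator; estimators never read it).
#' @param K number of visits; defaults to the number of \code{A} columns.
#' @param admin_censor_time administrative censoring time (default \code{K}).
#' @return object of class \code{longitudinal_cohort} (a data.frame).
#' @export
longitudinal_cohort <- function(data, K = NULL, admin_censor_time = NULL) {
  stopifnot(is.data.frame(data))
  if (is.null(K)) {
    K <- sum(grepl("^A[0-9]+$", names(data)))
    if (K == 0L) stop("no treatment columns A0..A{K-1} found")
  }
  if (is.null(admin_censor_time)) admin_censor_time <- K
  obj <- structure(as.data.frame(data),
                   K = as.integer(K),
                   admin_censor_time = as.numeric(admin_censor_time),
                   class = c("longitudinal_cohort", "data.frame"))
  validate_cohort(obj)
  obj
}

#' Validate a longitudinal cohort
#'
#' Checks the container invariants: required columns, event times in
#' \code{[0, admin_censor_time]}, binary treatment, treatment and covariate
#' values present exactly at survived visits, and (optionally) that treatment
#' is absorbing.
#'
#' @param cohort a \code{longitudinal_cohort}.
#' @param absorbing if \code{TRUE}, additionally require A monotone in k.
#' @return the cohort, invisibly.
#' @export
validate_cohort <- function(cohort, absorbing = FALSE) {
  K <- n_visits(cohort)
  tau <- admin_censor_time(cohort)
  need <- c("id", paste0("A", 0:(K - 1)), paste0("L", 0:(K - 1)), "time", "event")
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0)
    stop("cohort is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$id)) stop("duplicate individual ids")
  bad <- cohort$time < 0 | cohort$time > tau | !is.finite(cohort$time)
  if (any(bad))
    stop("event/censoring times outside [0, ", tau, "] for ids: ",
         paste(utils::head(cohort$id[bad], 5), collapse = ", "))
  if (!all(cohort$event %in% c(0, 1))) stop("event indicator must be 0/1")
  nv <- visits_survived(cohort)
  for (k in 0:(K - 1)) {
    a <- cohort[[paste0("A", k)]]
    l <- cohort[[paste0("L", k)]]
    seen <- nv > k
    if (any(seen & (is.na(a) | is.na(l))))
      stop("missing A", k, "/L", k, " at a survived visit for ids: ",
           paste(utils::head(cohort$id[seen & (is.na(a) | is.na(l))], 5),
                 collapse = ", "))
    if (!all(a[seen] %in% c(0, 1)))
      stop("treatment A", k, " outside {0,1} for ids: ",
           paste(utils::head(cohort$id[seen & !(a %in% c(0, 1))], 5),
                 collapse = ", "))
  }
  if (absorbing) {
    am <- treatment_matrix(cohort)
    drop <- which(apply(am, 1L, function(x) {
      x <- x[!is.na(x)]
      length(x) > 1 && any(diff(x) < 0)
    }))
    if (length(drop) > 0)
      stop("treatment is not absorbing for ids: ",
           paste(utils::head(cohort$id[drop], 5), collapse = ", "))
  }
  invisible(cohort)
}

#' @rdname longitudinal_cohort
#' @export
n_visits <- function(cohort) attr(cohort, "K")

#' @rdname longitudinal_cohort
#' @export
admin_censor_time <- function(cohort) attr(cohort, "admin_censor_time")

# number of visits survived to: visits k with k < time, capped at K
visits_survived <- function(cohort) {
  K <- n_visits(cohort)
  pmin(ceiling(cohort$time), K)
}

treatment_matrix <- function(cohort) {
  K <- n_visits(cohort)
  as.matrix(cohort[paste0("A", 0:(K - 1))])
}

covariate_matrix <- function(cohort) {
  K <- n_visits(cohort)
  as.matrix(cohort[paste0("L", 0:(K - 1))])
}

#' Read / write a longitudinal cohort as wide CSV
#'
#' The wide layout has one row per individual with columns \code{id},
#' \code{A0..A{K-1}}, \code{L0..L{K-1}}, \code{time}, \code{event} and any
#' extra columns.  An optional \code{schema} renames user columns to the
#' canonical names, e.g. \code{c(time = "followup_years")} maps the file's
#' \code{followup_years} onto \code{time}.
#'
#' @param path CSV file path.
#' @param schema named character vector: canonical name -> column name in file.
#' @param K,admin_censor_time see [longitudinal_cohort()].
#' @return [read_cohort()] a \code{longitudinal_cohort};
#'   [write_cohort()] the path, invisibly.
#' @export
read_cohort <- function(path, schema = NULL, K = NULL, admin_censor_time = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(schema)) {
    miss <- setdiff(unname(schema), names(dat))
    if (length(miss) > 0)
      stop("schema refers to absent columns: ", paste(miss, collapse = ", "))
    for (canon in names(schema)) {
      names(dat)[names(dat) == schema[[canon]]] <- canon
    }
  }
  longitudinal_cohort(dat, K = K, admin_censor_time = admin_censor_time)
}

#' @rdname read_cohort
#' @param cohort a \code{longitudinal_cohort}.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Specify a deterministic treatment regime
#'
#' A regime assigns a fixed treatment value a(k) at every visit k.  The two
#' regimes of primary interest are "always" (a(k) = 1 for all k, i.e. start
#' treatment at time 0 and sustain it) and "never" (a(k) = 0 throughout).
#'
#' @param label one of \code{"always"}, \code{"never"}, \code{"custom"}.
#' @param a for custom regimes, a 0/1 vector of length K giving a(k).
#' @param K number of visits.
#' @return object of class \code{regime_spec}: list with \code{label} and
#'   \code{a}, the length-K assignment vector.
#' @export
regime_spec <- function(label = c("always", "never", "custom"), a = NULL, K = 5L) {
  label <- match.arg(label)
  a <- switch(label,
              always = rep(1L, K),
              never  = rep(0L, K),
              custom = {
                if (is.null(a)) stop("custom regime requires `a`")
                as.integer(a)
              })
  if (!all(a %in% c(0L, 1L))) stop("regime values must be 0/1")
  structure(list(label = label, a = a, K = length(a)), class = "regime_spec")
}
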