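#' Cross-tabulate two-visit binary records into causal-tree counts
#'
#' For the two-visit setting with binary confounder and treatment
#' (L0, A0 measured at time 0; survival Y1 assessed at time 1; L1, A1
#' measured at time 1 among survivors; Y2 assessed at time 2), tabulates
#' the number of individuals along every pathway of the causal tree.
#'
#' @param data data.frame with 0/1 columns \code{L0, A0, Y1, L1, A1, Y2};
#'   \code{L1, A1, Y2} must be \code{NA} exactly where \code{Y1 = 1}.
#' @return object of class \code{causal_tree_counts}: list of count arrays
#'   \code{n}, \code{n_l0} [l0], \code{n_l0a} [l0, a0],
#'   \code{n_l0a_y1} [l0, a0, y1], and (among Y1 = 0 survivors)
#'   \code{n_l0a_l1} [l0, a0, l1], \code{n_l0a_l1a1} [l0, a0, l1, a1],
#'   \code{n_l0a_l1a1_y2} [l0, a0, l1, a1, y2]; indices are value + 1.
#' @export
tree_counts <- function(data) {
  need <- c("L0", "A0", "Y1", "L1", "A1", "Y2")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  chk <- function(x, nm, allow_na = FALSE) {
    ok <- x %in% c(0, 1) | (allow_na & is.na(x))
    if (!all(ok)) stop("non-binary values in ", nm)
  }
  chk(data$L0, "L0"); chk(data$A0, "A0"); chk(data$Y1, "Y1")
  for (nm in c("L1", "A1", "Y2")) {
    chk(data[[nm]], nm, allow_na = TRUE)
    if (any(is.na(data[[nm]]) != (data$Y1 == 1)))
      stop(nm, " must be present exactly where Y1 = 0")
  }
  tab <- function(...) {
    f <- lapply(list(...), factor, levels = 0:1)
    table(f, dnn = NULL)
  }
  s <- data[data$Y1 == 0, , drop = FALSE]
  structure(list(
    n = nrow(data),
    n_l0 = as.vector(tab(data$L0)),
    n_l0a = unclass(tab(data$L0, data$A0)),
    n_l0a_y1 = unclass(tab(data$L0, data$A0, data$Y1)),
    n_l0a_l1 = unclass(tab(s$L0, s$A0, s$L1)),
    n_l0a_l1a1 = unclass(tab(s$L0, s$A0, s$L1, s$A1)),
    n_l0a_l1a1_y2 = unclass(tab(s$L0, s$A0, s$L1, s$A1, s$Y2))),
    class = "causal_tree_counts")
}

check_pos <- function(x, what) {
  if (any(x == 0))
    stop("positivity violation: zero count in ", what)
  x
}

#' Nonparametric MSM-IPTW survival estimate on the causal tree
#'
#' Horvitz-Thompson style inverse-probability-of-treatment estimate of the
#' counterfactual survival probability under sustained treatment value
#' \code{a}:
#' horizon 1 (survival to time 1) sums, over the L0 strata, the survivor
#' fraction among the treated-as-\code{a} weighted by the stratum
#' frequency; horizon 2 (survival to time 2 under \code{a} at both visits)
#' extends the product over the four (L0, L1) histories.
#'
#' @param counts a \code{causal_tree_counts}.
#' @param a treatment value 0 or 1.
#' @param horizon 1 or 2.
#' @return estimated probability.
#' @export
np_msm_iptw <- function(counts, a, horizon = c(1, 2)) {
  horizon <- match.arg(as.character(horizon), c("1", "2"))
  ai <- a + 1L
  with(counts, {
    if (horizon == "1") {
      check_pos(n_l0a[, ai], "n_{l0, A0=a}")
      sum(n_l0a_y1[, ai, 1L] / n_l0a[, ai] * n_l0 / n)
    } else {
      check_pos(n_l0a[, ai], "n_{l0, A0=a}")
      check_pos(n_l0a_l1a1[, ai, , ai], "n_{l0 a, l1, A1=a}")
      tot <- 0
      for (l0 in 1:2) for (l1 in 1:2)
        tot <- tot + n_l0a_l1a1_y2[l0, ai, l1, ai, 1L] *
          (n_l0[l0] / n_l0a[l0, ai]) *
          (n_l0a_l1[l0, ai, l1] / n_l0a_l1a1[l0, ai, l1, ai])
      tot / n
    }
  })
}

#' Nonparametric sequential-trials survival estimate on the causal tree
#'
#' Trial 0 estimates stratum-specific survival given (A0 = a, L0) and
#' standardizes over the L0 distribution; at horizon 2 it multiplies the
#' first-period conditional survival by the second-period survival among
#' continuers, weighted by the inverse probability of remaining on the
#' baseline arm at visit 1 (the artificial-censoring weight) — which is
#' algebraically identical to the MSM-IPTW estimate at both horizons.
#' Trial 1 (restricted to A0 = 0, Y1 = 0 survivors) estimates one-period
#' survival standardized over the L1 distribution of its own trial
#' population, or, with \code{standardize_to_L0 = TRUE}, re-weighted to the
#' time-zero L0 distribution.
#'
#' @param counts a \code{causal_tree_counts}.
#' @param a treatment value 0 or 1.
#' @param horizon 1 or 2 (trial 0); trial 1 supports horizon 1 only
#'   (one period of follow-up from its start at time 1).
#' @param trial 0 or 1.
#' @param standardize_to_L0 trial 1 only: standardize to the L0
#'   distribution at time 0 instead of the trial-1 L1 distribution.
#' @return estimated probability.
#' @export
np_seqtrial <- function(counts, a, horizon = c(1, 2), trial = 0,
                        standardize_to_L0 = FALSE) {
  horizon <- match.arg(as.character(horizon), c("1", "2"))
  ai <- a + 1L
  if (trial == 0) {
    with(counts, {
      check_pos(n_l0a[, ai], "n_{l0, A0=a}")
      # conditional one-period survival per L0 stratum
      s1_l0 <- n_l0a_y1[, ai, 1L] / n_l0a[, ai]
      if (horizon == "1") return(sum(s1_l0 * n_l0 / n))
      check_pos(n_l0a_l1a1[, ai, , ai], "n_{l0 a, l1, A1=a}")
      # IPACW-weighted second-period survival among survivors, per L0
      s2_l0 <- vapply(1:2, function(l0) {
        surv <- n_l0a_y1[l0, ai, 1L]   # n_{l0 a, Y1=0}
        sum(n_l0a_l1a1_y2[l0, ai, , ai, 1L] *
              n_l0a_l1[l0, ai, ] / n_l0a_l1a1[l0, ai, , ai]) / surv
      }, numeric(1))
      sum(s2_l0 * s1_l0 * n_l0 / n)
    })
  } else if (trial == 1) {
    if (horizon != "1")
      stop("trial 1 starts at time 1; only one period of follow-up exists")
    with(counts, {
      # restricted to A0 = 0, Y1 = 0; strata on L1 (empty strata collapse)
      n_l1 <- apply(n_l0a_l1[, 1L, , drop = FALSE], 3, sum)
      n_l1a <- apply(n_l0a_l1a1[, 1L, , ai, drop = FALSE], 3, sum)
      n_l1a_y2 <- apply(n_l0a_l1a1_y2[, 1L, , ai, 1L, drop = FALSE], 3, sum)
      occ <- n_l1 > 0
      check_pos(n_l1a[occ], "n_{A0=0, l1, A1=a}")
      s_l1 <- ifelse(occ, n_l1a_y2 / pmax(n_l1a, 1), 0)
      if (standardize_to_L0) sum(s_l1 * n_l0 / n)
      else {
        n_surv <- sum(n_l0a_y1[, 1L, 1L])
        sum(s_l1 * n_l1 / n_surv)
      }
    })
  } else stop("trial must be 0 or 1")
}

#' Inverse-variance-weighted combination of two trial estimates
#'
#' @param est0,est1 lists with elements \code{estimate} and \code{variance}
#'   (variances e.g. from a nonparametric bootstrap over individuals).
#' @return list with the combined \code{estimate}, \code{variance} and the
#'   \code{weights} given to the two inputs.
#' @export
combine_trials <- function(est0, est1) {
  v <- c(est0$variance, est1$variance)
  e <- c(est0$estimate, est1$estimate)
  if (any(v < 0) || anyNA(v)) stop("variances must be nonnegative")
  if (any(v == 0)) {
    if (all(v == 0)) {
      warning("zero variances; falling back to the simple mean")
      return(list(estimate = mean(e), variance = 0, weights = c(0.5, 0.5)))
    }
    w <- as.numeric(v == 0)
  } else if (any(is.infinite(v))) {
    w <- as.numeric(is.finite(v))
  } else {
    w <- (1 / v)
  }
  w <- w / sum(w)
  list(estimate = sum(w * e),
       variance = if (all(v > 0) && all(is.finite(v))) 1 / sum(1 / v)
                  else sum(w^2 * v),
       weights = w)
}

#' Read / write causal-tree counts as a flat CSV
#'
#' @param counts a \code{causal_tree_counts}.
#' @param path CSV path with columns \code{cell}, \code{count}, where
#'   \code{cell} encodes the indices, e.g. \code{"n_l0a_y1[1,2,1]"}.
#' @return [write_tree_counts()] the path invisibly; [read_tree_counts()]
#'   a \code{causal_tree_counts}.
#' @export
write_tree_counts <- function(counts, path) {
  rows <- list(data.frame(cell = "n", count = counts$n))
  for (nm in setdiff(names(counts), "n")) {
    arr <- counts[[nm]]
    idx <- which(arr >= 0, arr.ind = TRUE)
    if (is.null(dim(arr))) idx <- matrix(seq_along(arr), ncol = 1)
    lab <- apply(idx, 1L, function(i)
      paste0(nm, "[", paste(i, collapse = ","), "]"))
    rows[[nm]] <- data.frame(cell = lab, count = as.vector(arr[idx]))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_counts
#' @export
read_tree_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dims <- list(n_l0 = 2L, n_l0a = c(2L, 2L), n_l0a_y1 = c(2L, 2L, 2L),
               n_l0a_l1 = c(2L, 2L, 2L), n_l0a_l1a1 = c(2L, 2L, 2L, 2L),
               n_l0a_l1a1_y2 = c(2L, 2L, 2L, 2L, 2L))
  out <- list(n = df$count[df$cell == "n"])
  for (nm in names(dims)) {
    arr <- array(0, dim = dims[[nm]])
    sel <- grepl(paste0("^", nm, "\\["), df$cell)
    for (r in which(sel)) {
      i <- as.integer(strsplit(sub(".*\\[(.*)\\]", "\\1", df$cell[r]), ",")[[1]])
      arr[matrix(i, 1)] <- df$count[r]
    }
    out[[nm]] <- if (nm == "n_l0") as.vector(arr) else arr
  }
  structure(out, class = "causal_tree_counts")
}
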