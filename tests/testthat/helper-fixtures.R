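# Small hand-built cohorts and generators shared across tests.

# four-individual cohort with K = 2 visits, binary L, chosen so that all
# weight-model cells are occupied; used for enumeration oracles
toy_cohort_k2 <- function() {
  # id 1: L0=0, A0=0, survives, L1=0, A1=0, censored at 2
  # id 2: L0=0, A0=1, event at 1.5
  # id 3: L0=1, A0=0, survives, L1=1, A1=1, censored at 2
  # id 4: L0=1, A0=1, survives, L1=0, A1=1 (absorbing), event at 1.25
  df <- data.frame(
    id = 1:4,
    A0 = c(0, 1, 0, 1), A1 = c(0, NA, 1, 1),
    L0 = c(0, 0, 1, 1), L1 = c(0, NA, 1, 0),
    time = c(2, 1.5, 2, 1.25), event = c(0, 1, 0, 1))
  df$A1[2] <- NA; df$L1[2] <- NA
  # id 2 has the event in (1, 1.5] so visit 1 is survived to: fill values
  df$A1[2] <- 1; df$L1[2] <- 1
  longitudinal_cohort(df, K = 2, admin_censor_time = 2)
}

# cohort with binary L drawn from saturated conditional probabilities, for
# count-ratio oracles on the weight models
simulate_binary_cohort <- function(n, seed, pA_given_L = c(`0` = 0.3, `1` = 0.6),
                                   pL1 = 0.4, haz = 0.15, K = 3) {
  set.seed(seed)
  L <- matrix(rbinom(n * K, 1, pL1), n, K)
  A <- matrix(0L, n, K)
  A[, 1] <- rbinom(n, 1, pA_given_L[as.character(L[, 1])])
  for (k in 2:K)
    A[, k] <- pmax(A[, k - 1],
                   rbinom(n, 1, pA_given_L[as.character(L[, k])]))
  e <- rexp(n)
  tim <- pmin(e / haz, K)
  ev <- as.integer(e / haz < K)
  nv <- pmin(ceiling(tim), K)
  for (k in 2:K) {
    unseen <- nv < k
    L[unseen, k] <- NA; A[unseen, k] <- NA
  }
  df <- data.frame(id = seq_len(n))
  for (k in 0:(K - 1)) df[[paste0("A", k)]] <- A[, k + 1]
  for (k in 0:(K - 1)) df[[paste0("L", k)]] <- L[, k + 1]
  df$time <- tim; df$event <- ev
  longitudinal_cohort(df, K = K, admin_censor_time = K)
}

# independent per-individual loop computing expected person-period row count
expected_pp_rows <- function(cohort) {
  K <- n_visits(cohort)
  sum(vapply(seq_len(nrow(cohort)), function(i) {
    tt <- cohort$time[i]
    length(seq_len(min(ceiling(tt), K)))
  }, numeric(1)))
}

# random positive causal-tree count table (all cells >= 1)
random_tree_counts <- function(seed, size = 2000) {
  set.seed(seed)
  repeat {
    l0 <- rbinom(size, 1, runif(1, 0.3, 0.7))
    a0 <- rbinom(size, 1, plogis(-0.5 + 1.2 * l0 + rnorm(1, 0, 0.3)))
    y1 <- rbinom(size, 1, plogis(-1.5 + 0.8 * l0 - 0.6 * a0))
    l1 <- ifelse(y1 == 1, NA, rbinom(size, 1, plogis(-0.3 + l0 - 0.5 * a0)))
    a1 <- ifelse(y1 == 1, NA,
                 rbinom(size, 1, plogis(-0.5 + 0.8 * a0 + 1.1 * ifelse(is.na(l1), 0, l1))))
    y2 <- ifelse(y1 == 1, NA, rbinom(size, 1, plogis(-1.2 + 0.7 * ifelse(is.na(l1), 0, l1) - 0.5 * ifelse(is.na(a1), 0, a1))))
    dat <- data.frame(L0 = l0, A0 = a0, Y1 = y1, L1 = l1, A1 = a1, Y2 = y2)
    ct <- tree_counts(dat)
    # require full positivity so the estimators are defined for both arms
    if (all(ct$n_l0a > 0) && all(ct$n_l0a_y1[, , 1] > 0) &&
        all(ct$n_l0a_l1 > 0) && all(ct$n_l0a_l1a1 > 0))
      return(ct)
  }
}
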