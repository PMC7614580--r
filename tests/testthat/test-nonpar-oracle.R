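test_that("tree counts equal an independent nested-loop tabulation", {
  ct <- random_tree_counts(seed = 71, size = 500)
  set.seed(72)
  # independent tabulation on fresh data
  n <- 400
  l0 <- rbinom(n, 1, 0.5); a0 <- rbinom(n, 1, 0.4)
  y1 <- rbinom(n, 1, 0.2)
  l1 <- ifelse(y1 == 1, NA, rbinom(n, 1, 0.5))
  a1 <- ifelse(y1 == 1, NA, rbinom(n, 1, 0.5))
  y2 <- ifelse(y1 == 1, NA, rbinom(n, 1, 0.3))
  dat <- data.frame(L0 = l0, A0 = a0, Y1 = y1, L1 = l1, A1 = a1, Y2 = y2)
  ct2 <- tree_counts(dat)
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    expect_equal(ct2$n_l0a_y1[i + 1, j + 1, k + 1],
                 sum(l0 == i & a0 == j & y1 == k))
    expect_equal(ct2$n_l0a_l1[i + 1, j + 1, k + 1],
                 sum(l0 == i & a0 == j & y1 == 0 & l1 == k, na.rm = TRUE))
  }
  expect_equal(sum(ct2$n_l0), ct2$n)
  expect_error(tree_counts(transform(dat, A0 = A0 + 2)), "non-binary")
  expect_error(tree_counts(transform(dat, L1 = ifelse(is.na(L1), 0, L1))),
               "exactly where")
})

test_that("the worked horizon-1 table evaluates to 0.72", {
  ct <- structure(list(
    n = 100,
    n_l0 = c(60, 40),
    n_l0a = matrix(c(30, 20, 30, 20), 2),     # [l0, a0]: untreated 30/20
    n_l0a_y1 = array(0, c(2, 2, 2)),
    n_l0a_l1 = array(1, c(2, 2, 2)),
    n_l0a_l1a1 = array(1, c(2, 2, 2, 2)),
    n_l0a_l1a1_y2 = array(1, c(2, 2, 2, 2, 2))),
    class = "causal_tree_counts")
  ct$n_l0a <- matrix(c(30, 20, 30, 20), 2)    # treated counts 30 and 20
  ct$n_l0a_y1[, 2, 1] <- c(24, 12)            # survivors among treated
  ct$n_l0a_y1[, 1, 1] <- c(21, 10)            # survivors among untreated
  est <- np_msm_iptw(ct, a = 1, horizon = 1)
  expect_equal(est, (24 / 30) * (60 / 100) + (12 / 20) * (40 / 100))
  expect_equal(est, 0.72)
  # sequential-trials trial 0 gives the identical number
  expect_equal(np_seqtrial(ct, a = 1, horizon = 1, trial = 0), est)
})

test_that("no confounding collapses the estimate to the crude proportion", {
  set.seed(73)
  n <- 5000
  l0 <- rbinom(n, 1, 0.5)
  a0 <- rbinom(n, 1, 0.4)              # independent of L0
  y1 <- rbinom(n, 1, 0.25)             # independent of A0 and L0
  dat <- data.frame(L0 = l0, A0 = a0, Y1 = y1,
                    L1 = ifelse(y1 == 1, NA, 0),
                    A1 = ifelse(y1 == 1, NA, a0),
                    Y2 = ifelse(y1 == 1, NA, 0))
  ct <- tree_counts(dat)
  est <- np_msm_iptw(ct, a = 1, horizon = 1)
  # treatment independent of L0, survival independent of A: the weighted
  # estimate equals the crude survivor proportion among the treated, which
  # in turn is close to the overall crude proportion
  crude <- sapply(0:1, function(l) mean(dat$Y1[dat$A0 == 1 & dat$L0 == l] == 0))
  direct <- sum(crude * ct$n_l0 / ct$n)
  expect_equal(est, direct, tolerance = 1e-12)
  expect_lt(abs(est - mean(dat$Y1 == 0)), 0.03)
})

test_that("MSM-IPTW and trial-0 sequential estimates coincide exactly", {
  for (s in 1:25) {
    ct <- random_tree_counts(seed = 100 + s, size = 800)
    for (a in 0:1) {
      expect_equal(np_seqtrial(ct, a, 1, trial = 0), np_msm_iptw(ct, a, 1),
                   tolerance = 1e-14)
      expect_equal(np_seqtrial(ct, a, 2, trial = 0), np_msm_iptw(ct, a, 2),
                   tolerance = 1e-14)
      expect_true(np_msm_iptw(ct, a, 2) >= 0 && np_msm_iptw(ct, a, 2) <= 1)
    }
  }
})

test_that("the model-based weighted pipeline reproduces the tree estimates", {
  # saturated logistic weights + Horvitz-Thompson sums equal the exact
  # nonparametric values: the cross-module consistency oracle
  set.seed(74)
  n <- 3000
  l0 <- rbinom(n, 1, 0.5)
  a0 <- rbinom(n, 1, plogis(-0.5 + l0))
  y1 <- rbinom(n, 1, plogis(-1.5 + 0.5 * l0 - 0.4 * a0))
  l1 <- ifelse(y1 == 1, NA, rbinom(n, 1, plogis(-0.2 + 0.8 * l0)))
  a1 <- ifelse(y1 == 1, NA, pmax(a0, rbinom(n, 1, plogis(-1 + ifelse(is.na(l1), 0, l1)))))
  y2 <- ifelse(y1 == 1, NA, rbinom(n, 1, plogis(-1 + 0.5 * ifelse(is.na(l1), 0, l1))))
  dat <- data.frame(L0 = l0, A0 = a0, Y1 = y1, L1 = l1, A1 = a1, Y2 = y2)
  ct <- tree_counts(dat)
  # horizon 1: saturated logistic model for A0 given L0
  m0 <- glm(A0 ~ factor(L0), family = binomial(), data = dat)
  p0 <- predict(m0, type = "response")
  for (a in 0:1) {
    pa <- if (a == 1) p0 else 1 - p0
    ht <- mean((dat$A0 == a) * (1 - dat$Y1) / pa)
    expect_equal(ht, np_msm_iptw(ct, a, 1), tolerance = 1e-10)
  }
  # horizon 2 for the always-treated arm: product of saturated probabilities
  s <- dat$Y1 == 0
  m1 <- suppressWarnings(glm(A1 ~ factor(L0) * factor(L1), family = binomial(),
            data = dat[s & dat$A0 == 1, ]))
  p1 <- rep(NA_real_, n)
  p1[s & dat$A0 == 1] <- predict(m1, type = "response")
  ht2 <- sum(ifelse(s & dat$A0 == 1 & dat$A1 == 1,
                    (1 - dat$Y2) / (p0 * p1), 0), na.rm = TRUE) / n
  expect_equal(ht2, np_msm_iptw(ct, 1, 2), tolerance = 1e-10)
})

test_that("trial-1 estimates stratify and standardize as displayed", {
  ct <- random_tree_counts(seed = 75, size = 1500)
  # degenerate L1 (constant 0): relabel stratum 2 into stratum 1, which
  # collapses the estimate to a single pooled stratum proportion
  ct2 <- ct
  ct2$n_l0a_l1[, , 1] <- ct2$n_l0a_l1[, , 1] + ct2$n_l0a_l1[, , 2]
  ct2$n_l0a_l1[, , 2] <- 0
  ct2$n_l0a_l1a1[, , 1, ] <- ct2$n_l0a_l1a1[, , 1, ] + ct2$n_l0a_l1a1[, , 2, ]
  ct2$n_l0a_l1a1[, , 2, ] <- 0
  ct2$n_l0a_l1a1_y2[, , 1, , ] <- ct2$n_l0a_l1a1_y2[, , 1, , ] +
    ct2$n_l0a_l1a1_y2[, , 2, , ]
  ct2$n_l0a_l1a1_y2[, , 2, , ] <- 0
  est <- np_seqtrial(ct2, a = 1, horizon = 1, trial = 1)
  num <- sum(ct2$n_l0a_l1a1_y2[, 1, 1, 2, 1])
  den <- sum(ct2$n_l0a_l1a1[, 1, 1, 2])
  expect_equal(est, num / den, tolerance = 1e-14)
  # standardized version reweights strata by the L0 law
  est_std <- np_seqtrial(ct, a = 1, horizon = 1, trial = 1,
                         standardize_to_L0 = TRUE)
  s_l1 <- vapply(1:2, function(l1)
    sum(ct$n_l0a_l1a1_y2[, 1, l1, 2, 1]) / sum(ct$n_l0a_l1a1[, 1, l1, 2]),
    numeric(1))
  expect_equal(est_std, sum(s_l1 * ct$n_l0 / ct$n), tolerance = 1e-14)
  expect_error(np_seqtrial(ct, 1, 2, trial = 1), "one period")
})

test_that("inverse-variance combination behaves at its limits", {
  e0 <- list(estimate = 0.8, variance = 0.01)
  e1 <- list(estimate = 0.6, variance = 0.01)
  cmb <- combine_trials(e0, e1)
  expect_equal(cmb$estimate, 0.7)                       # equal variances
  expect_equal(sum(cmb$weights), 1)
  expect_equal(cmb$variance, 1 / (1 / 0.01 + 1 / 0.01)) # pooled variance
  # infinite variance: the other estimate is returned
  cmb2 <- combine_trials(e0, list(estimate = 0.6, variance = Inf))
  expect_equal(cmb2$estimate, 0.8)
  expect_warning(combine_trials(list(estimate = 1, variance = 0),
                                list(estimate = 0, variance = 0)), "zero")
})

test_that("counts survive a CSV round trip", {
  ct <- random_tree_counts(seed = 76, size = 300)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tree_counts(ct, path)
  back <- read_tree_counts(path)
  expect_equal(back$n, ct$n)
  expect_equal(back$n_l0, as.vector(ct$n_l0))
  expect_equal(unclass(back$n_l0a_l1a1_y2), unclass(ct$n_l0a_l1a1_y2),
               ignore_attr = TRUE)
})
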