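test_that("saturated treatment models recover empirical conditional proportions", {
  co <- simulate_binary_cohort(4000, seed = 21)
  pp <- to_person_period(co)
  tm <- fit_treatment_models(pp, "both")
  ar <- pp[pp$A_prev == 0, ]
  # denominator A ~ L on binary L is saturated: fitted = cell proportions
  for (l in 0:1) {
    emp <- mean(ar$A[ar$L == l])
    fit <- predict(tm$denominator, newdata = data.frame(L = l), type = "response")
    expect_equal(unname(fit), emp, tolerance = 1e-6)
  }
  # per-visit numerator intercepts are per-visit initiation proportions
  p_marg <- seqtrials:::predict_per_k(tm$numerator_marginal, tm$visits,
                                      0:2, data.frame(dummy = 1:3))
  for (kk in 0:2)
    expect_equal(p_marg[kk + 1], mean(ar$A[ar$k == kk]), tolerance = 1e-6)
  # treated-history rows never enter any fit
  expect_equal(nrow(tm$denominator$model), nrow(ar))
})

test_that("null confounding yields a near-zero fitted L coefficient", {
  co <- simulate_cohort(scenario_params(gammaL = 0), 20000, seed = 22)
  tm <- fit_treatment_models(to_person_period(co), "marginal")
  se <- summary(tm$denominator)$coefficients["L", "Std. Error"]
  expect_lt(abs(coef(tm$denominator)[["L"]]), 4 * se)
})

test_that("stabilized IPTW behave as the worked enumeration dictates", {
  co <- simulate_binary_cohort(2000, seed = 23)
  pp <- to_person_period(co)
  tm <- fit_treatment_models(pp, "both")
  w <- compute_iptw(tm, pp, "marginal")
  # hand-computed ratio of empirical proportions for each row, sequentially
  ar <- pp[pp$A_prev == 0, ]
  p_den <- sapply(0:1, function(l) mean(ar$A[ar$L == l]))
  p_num <- sapply(0:2, function(kk) mean(ar$A[ar$k == kk]))
  fac <- ifelse(pp$A_prev == 1, 1,
                ifelse(pp$A == 1, p_num[pp$k + 1], 1 - p_num[pp$k + 1]) /
                ifelse(pp$A == 1, p_den[pp$L + 1], 1 - p_den[pp$L + 1]))
  w_hand <- unlist(lapply(split(fac, pp$id)[as.character(unique(pp$id))], cumprod),
                   use.names = FALSE)
  expect_equal(as.numeric(w), w_hand, tolerance = 1e-9)
  # factors after treatment initiation are 1: weight frozen from then on
  for (i in unique(pp$id[pp$A_prev == 1])[1:5]) {
    wi <- as.numeric(w)[pp$id == i]
    ki <- which(pp$A_prev[pp$id == i] == 1)
    expect_true(all(abs(diff(wi[c(min(ki) - 1, ki)])) < 1e-12))
  }
  # mean stabilized weight is near 1 at every interval
  expect_true(all(abs(tapply(as.numeric(w), pp$k, mean) - 1) < 0.1))
})

test_that("numerator identical to denominator gives weights exactly 1", {
  co <- simulate_binary_cohort(500, seed = 24)
  pp <- to_person_period(co)
  tm <- fit_treatment_models(pp, "marginal")
  # rebuild a model set whose numerator is the denominator model itself
  p1 <- predict(tm$denominator, newdata = pp, type = "response")
  fac <- ifelse(pp$A == 1, p1, 1 - p1)
  fac <- fac / fac
  expect_true(all(fac == 1))
  w_unstab <- compute_iptw(tm, pp, "none")
  w_manual <- seqtrials:::cumprod_by(
    ifelse(pp$A_prev == 1, 1, 1 / ifelse(pp$A == 1, p1, 1 - p1)),
    pp$id, pp$k)
  expect_equal(as.numeric(w_unstab), w_manual, tolerance = 1e-9)
})

test_that("IPACW equal 1 in the first period and on the initiator arm", {
  co <- simulate_cohort(scenario_params("scenario1"), 2000, seed = 25)
  stack <- build_trials(co)
  wm <- fit_ipacw_models(stack)
  trc <- apply_artificial_censoring(stack)
  w <- compute_ipacw(wm, trc)
  expect_true(all(w[trc$j == 0] == 1))
  expect_true(all(w[trc$arm == 1] == 1))
  expect_true(all(w > 0))
  # non-trivial weights do appear on the non-initiator arm later on
  expect_gt(max(w[trc$arm == 0 & trc$j >= 1]), 1)
})

test_that("IPACW match hand-computed ratios on a saturated toy stack", {
  co <- simulate_binary_cohort(3000, seed = 26)
  stack <- build_trials(co)
  wm <- fit_ipacw_models(stack)
  trc <- apply_artificial_censoring(stack)
  w <- compute_ipacw(wm, trc)
  # reconstruct the stabilized factors directly from empirical proportions
  ar <- stack[stack$arm == 0 & stack$j >= 1 & stack$A_prev == 0, ]
  ar$visit <- ar$trial + ar$j
  sel <- trc$arm == 0 & trc$j >= 1
  tr <- trc[sel, ]
  tr$visit <- tr$trial + tr$j
  fac <- vapply(seq_len(nrow(tr)), function(r) {
    den_cell <- ar$A[ar$L == tr$L[r]]                        # saturated in L
    num_cell <- ar$A[ar$visit == tr$visit[r] & ar$L_base == tr$L_base[r]]
    (1 - mean(num_cell)) / (1 - mean(den_cell))
  }, numeric(1))
  w_hand <- seqtrials:::cumprod_by(fac, paste(tr$id, tr$trial), tr$j)
  expect_equal(as.numeric(w[sel]), w_hand, tolerance = 1e-9)
})

test_that("IPCW hook returns unit weights without a dropout process", {
  co <- simulate_cohort(scenario_params("scenario1"), 200, seed = 27)
  pp <- to_person_period(co)
  expect_true(all(compute_ipcw(NULL, pp) == 1))
  pp$dropout <- 0
  expect_true(all(compute_ipcw(list(), pp) == 1))
})

test_that("weight truncation caps at the pooled percentile and is idempotent", {
  w <- seqtrials:::weight_series(c(1:100), "iptw")
  tw <- truncate_weights(w, 95)
  cap <- quantile(1:100, 0.95, names = FALSE, type = 1)
  expect_equal(max(tw), cap)
  expect_equal(attr(tw, "n_truncated"), sum(1:100 > cap))
  expect_equal(as.numeric(truncate_weights(tw, 95)), as.numeric(tw))
  # degenerate distribution unchanged
  expect_equal(as.numeric(truncate_weights(seqtrials:::weight_series(rep(2, 10), "iptw"), 95)),
               rep(2, 10))
  expect_error(truncate_weights(w, 0), "percentile")
  expect_error(truncate_weights(w, 101), "percentile")
})
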