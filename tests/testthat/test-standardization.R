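# hand-built additive fit with constant increments on a unit grid
constant_increment_fit <- function(slopes, times = seq(0.01, 5, by = 0.01),
                                   design = msm_design("current")) {
  p <- length(slopes)
  dB <- matrix(rep(slopes, each = length(times)) * 0.01, ncol = p)
  terms <- c("(Intercept)",
             switch(design$treatment, current = "A", arm = "arm",
                    none = NULL),
             design$covariates)
  colnames(dB) <- terms
  structure(list(times = times, dB = dB, B = apply(dB, 2, cumsum),
                 terms = terms, design = design, n_events = length(times),
                 n_skipped = 0L),
            class = "aalen_msm")
}

test_that("closed-form survival of a constant-increment additive fit", {
  # cumulative intercept slope 0.2, treatment slope -0.04: never-treated
  # survival at 5 is exp(-1)
  fit <- constant_increment_fit(c(0.2, -0.04))
  s0 <- survival_under_regime(fit, regime_spec("never"), times = 5)
  expect_equal(s0$S, exp(-1), tolerance = 1e-10)
  s1 <- survival_under_regime(fit, regime_spec("always"), times = 5)
  expect_equal(s1$S, exp(-(0.2 - 0.04) * 5), tolerance = 1e-10)
  # zero treatment coefficients: regimes coincide
  fit0 <- constant_increment_fit(c(0.2, 0))
  expect_equal(survival_under_regime(fit0, regime_spec("always"), times = 1:5)$S,
               survival_under_regime(fit0, regime_spec("never"), times = 1:5)$S)
})

test_that("survival matches direct numerical integration of the hazard path", {
  co <- simulate_cohort(scenario_params("scenario1"), 600, seed = 61)
  pp <- to_person_period(co)
  fit <- fit_aalen_msm(pp, msm_design("lags", covariates = "L0"))
  l0 <- 0.4
  s <- survival_under_regime(fit, regime_spec("always"),
                             newdata = data.frame(L0 = l0), times = 1:5)
  # independent evaluation: sum increments term by term over event times
  m <- ceiling(fit$times) - 1
  dH <- fit$dB[, "(Intercept)"] + l0 * fit$dB[, "L0"]
  # treatment under "always": sum of all active lag columns
  cols <- c("A", paste0("A_lag", 1:4))
  for (j in 0:4) dH <- dH + ifelse(m >= j, fit$dB[, cols[j + 1]], 0)
  H <- cumsum(dH)
  ref <- exp(-H[vapply(1:5, function(tt) max(which(fit$times <= tt)), integer(1))])
  expect_equal(s$S, pmin(ref, 1), tolerance = 1e-10)
})

test_that("standardization is exact averaging over member curves", {
  co <- simulate_cohort(scenario_params("scenario1"), 400, seed = 62)
  pp <- to_person_period(co)
  fit <- fit_aalen_msm(pp, msm_design("current", covariates = "L0"))
  pop <- data.frame(L0 = c(-1, 0, 0.5, 2))
  sm <- standardize_marginal(fit, regime_spec("always"), pop, times = 1:5)
  one_by_one <- rowMeans(sapply(pop$L0, function(l)
    survival_under_regime(fit, regime_spec("always"),
                          newdata = data.frame(L0 = l), times = 1:5)$S))
  expect_equal(sm$S, one_by_one, tolerance = 1e-12)
  # degenerate population: marginal equals the single conditional curve
  s1 <- standardize_marginal(fit, regime_spec("always"),
                             data.frame(L0 = rep(0.3, 7)), times = 1:5)
  sc <- survival_under_regime(fit, regime_spec("always"),
                              newdata = data.frame(L0 = 0.3), times = 1:5)
  expect_equal(s1$S, sc$S, tolerance = 1e-12)
})

test_that("standardized curves are invariant to affine recoding of L0", {
  co <- simulate_cohort(scenario_params("scenario1"), 800, seed = 63)
  pp <- to_person_period(co)
  w <- compute_iptw(fit_treatment_models(pp, "L0"), pp, "conditional_L0")
  f1 <- fit_aalen_msm(pp, msm_design("current", covariates = "L0"), w)
  s1 <- standardize_marginal(f1, regime_spec("always"),
                             data.frame(L0 = co$L0), times = 1:5)
  pp2 <- pp; pp2$L0 <- 2 * pp$L0 + 3
  f2 <- fit_aalen_msm(pp2, msm_design("current", covariates = "L0"), w)
  s2 <- standardize_marginal(f2, regime_spec("always"),
                             data.frame(L0 = 2 * co$L0 + 3), times = 1:5)
  expect_equal(s1$S, s2$S, tolerance = 1e-8)
})

test_that("risk differences obey their defining identities", {
  fit <- constant_increment_fit(c(0.2, -0.04))
  s1 <- survival_under_regime(fit, regime_spec("always"), times = c(0.5, 1:5))
  s0 <- survival_under_regime(fit, regime_spec("never"), times = c(0.5, 1:5))
  rd <- risk_difference(s1, s0, taus = c(0, 1, 3, 5))
  expect_equal(rd$RD[rd$t == 0], 0)            # S(0) = 1 for both regimes
  expect_equal(rd$RD, rd$S1 - rd$S0)
  expect_true(all(abs(rd$RD) <= 1))
  rd_same <- risk_difference(s1, s1, taus = 1:5)
  expect_true(all(rd_same$RD == 0))
  # mismatched populations refuse to combine
  s0b <- s0; attr(s0b, "population") <- "standardized"
  expect_error(risk_difference(s1, s0b), "population")
})

test_that("Cox and Aalen standardized curves agree under weak effects", {
  # with a small true effect the proportional-hazards and additive forms
  # are locally similar; the two model classes should give close curves
  co <- simulate_cohort(scenario_params("scenario1"), 3000, seed = 64)
  ea <- estimate_msm_iptw(co, 1:5, model = "aalen")
  ec <- estimate_msm_iptw(co, 1:5, model = "cox")
  expect_lt(max(abs(ea$S0 - ec$S0)), 0.03)
  expect_lt(max(abs(ea$RD - ec$RD)), 0.04)
})

test_that("both estimator pipelines emit monotone curves in [0, 1]", {
  co <- simulate_cohort(scenario_params("scenario1"), 2000, seed = 65)
  for (est in list(estimate_msm_iptw(co, 1:5),
                   estimate_seq_trials(co, 1:5))) {
    for (curve in list(est$curve1, est$curve0)) {
      expect_true(all(curve$S >= 0 & curve$S <= 1))
      expect_true(all(diff(curve$S) <= 1e-12))
    }
  }
})
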