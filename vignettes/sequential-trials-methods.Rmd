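---
title: "Estimating effects of sustained treatment strategies on survival: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating effects of sustained treatment strategies on survival: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqtrials)
```

## The problem

Longitudinal observational cohorts record, at regular visits k = 0, 1, ...,
a binary treatment status $A_k$, time-dependent covariates $L_k$, and a
continuous event or censoring time.  The causal question is a *per-protocol*
contrast: how would survival differ if everyone had started treatment at
time zero and stayed on it ("always treated", $\underline{a}_0 = 1$) versus
never starting it ("never treated", $\underline{a}_0 = 0$)?  The estimand is
the marginal risk difference at horizon $\tau$,

$$\mathrm{RD}(\tau) = \Pr(T^{\underline{a}_0=1} > \tau) - \Pr(T^{\underline{a}_0=0} > \tau),$$

reported so that positive values mean better survival under sustained
treatment, standardized to a stated reference population (by default the
study population at time zero).  The central difficulty is time-dependent
confounding: $L_k$ predicts both subsequent treatment initiation and the
outcome, and is itself affected by earlier treatment, so neither naive
regression adjustment nor baseline-only adjustment identifies the estimand.

Identification requires no interference, consistency, positivity and
sequential conditional exchangeability given $(\bar A_{k-1}, \bar L_k)$.
Both estimators in this package rely on exactly these assumptions and
target the same estimand, which is what makes their efficiency comparison
meaningful.

## The two estimators

**MSM-IPTW.**  A marginal structural model is posed for the hazard of the
counterfactual event time as a function of treatment history (and optionally
the baseline covariate $L_0$), and fitted to person-period data weighted by
stabilized inverse-probability-of-treatment weights: the cumulative product
over visits of (numerator probability of the observed treatment given
limited history) / (denominator probability given the confounder history).
Under an additive conditional hazard that depends on current treatment,
the correctly specified marginal additive MSM carries a separate
time-varying coefficient for treatment at each lag,
$\alpha_0(t) + \sum_{j=0}^{\lfloor t\rfloor} \tilde\alpha_{Aj}(t)\,
a_{\lfloor t\rfloor - j} (+ \alpha_L(t) L_0)$, which is the default design
(`msm_design("lags", covariates = "L0")`).

**Sequential trials.**  A trial is emulated from every visit: individuals
with no prior treatment enter trial k with arm = their observed $A_k$
(initiators versus non-initiators).  Follow-up within a trial is
artificially censored at the first visit where observed treatment deviates
from the arm, which makes arm a time-fixed covariate within trial, and the
informative censoring so introduced is corrected by inverse probability of
artificial-censoring weights (IPACW).  A single hazard MSM with a constant
arm term and the trial-baseline covariate $L_k$, with parameters common
across trials, is fitted to the pooled weighted stack
(`msm_design("arm", covariates = "L_base")`).  Pooling across trials reuses
non-initiators in several trials and is where the approach's efficiency
gains at early horizons come from; its cost is that individuals stop
contributing at deviation, thinning late follow-up.

Both hazard-model families are available: the weighted Aalen additive
model, whose cumulative coefficients are estimated at each event time by
weighted least squares over the at-risk rows, and the weighted Cox model
(partial likelihood via `survival::coxph`, weighted Breslow baseline
computed in-package at the covariate origin).  Additive-hazards parameters
are collapsible, so the additive MSMs of the two approaches can be — and
under the packaged data-generating mechanism are — simultaneously correctly
specified; Cox MSMs cannot in general, which is why the simulation study
and its truth comparisons use the additive model, and why the test suite
asserts unbiasedness only for the Aalen route.

**Standardization.**  Conditional fits are converted to marginal curves by
cloning: every member of the reference population is duplicated under each
regime with covariates held at the member's values, conditional survival
$\exp(-\hat H(\tau \mid \text{covariates}))$ is evaluated exactly on the
event-time step function, and averaged.  For the sequential-trials MSM the
clone's trial-baseline covariate is set to the member's $L_0$, so both
approaches standardize to the same time-zero population and the risk
differences are directly comparable.  Fitting once over all event times up
to $\tau_{\max}$ and reading off every $\tau$ from the same fit keeps each
clone's curve monotone.

**Inference.**  Nonparametric bootstrap over individuals (all rows of an
individual travel together), re-running trial formation, weight estimation,
MSM fitting and standardization in each resample; percentile intervals with
the type-7 quantile.

## The data-generating mechanism

`simulate_cohort()` draws, per individual, a frailty $U \sim N(0, 0.1)$
(the dispersion parameter is read as a variance, sd $= \sqrt{0.1}$ — the
interpretation is pinned by a calibration test reproducing the ~57%
scenario-1 event fraction), then per visit: $L_0 \sim N(U, 1)$,
$L_k \sim N(0.8 L_{k-1} - A_{k-1} + 0.1 k + U, 1)$; treatment initiation
$\text{logit}\Pr(A_k = 1 \mid A_{k-1} = 0, L_k) = \gamma_0 + \gamma_L L_k$
with treatment absorbing; and an event-time competition on each unit
interval under the conditional hazard
$h = 0.2 - 0.04 A_k + 0.015 L_k + 0.015 U$, piecewise constant between
visits, administratively censored at $t = 5$.  Scenario presets vary
$(\gamma_0, \gamma_L)$: (-1, 0.5) common initiation / moderate confounding,
(-3, 0.5) rare initiation, (-1, 3) strong confounding.  These generator
defaults are the published study conditions and are not tuning knobs.

Two details are deliberate:

* The conditional hazard can go (rarely) negative because the treatment
  coefficient is negative and $L$ is Gaussian; negative interval hazards
  are clipped to zero *in the generator only*, which preserves a valid
  survival process and affects an extreme tail of covariate paths.
* Event times are drawn by inverting the piecewise-exponential survivor
  function from a single standard-exponential draw, vectorized over
  individuals with one RNG call per visit from a single seeded stream.
  Draws for visits after death are generated and then masked, which leaves
  the joint distribution untouched and keeps generation reproducible and
  fast (per-individual RNG substreams were considered and rejected as
  needlessly slow in R).

Ground truth is computed as a large simulated randomized trial
(`compute_truth()`): the same frailty, baseline covariate and innovation
draws are reused for both forced regimes (common random numbers), and with
only administrative censoring the Kaplan-Meier estimate reduces to the
empirical survivor function, evaluated exactly.  The repository fixture
(`truth_fixture()`, N = 1e6) applies to all three scenarios because
treatment-assignment parameters do not enter the counterfactual world.

What the generator does *not* emulate: irregular visit schedules,
measurement error, loss to follow-up (an IPCW hook exists but the
simulation has no dropout), competing events, non-absorbing treatment, or
covariate-dependent eligibility windows.  Passing tests therefore show
correctness of the estimators under regular, completely observed,
absorbing-treatment data — not robustness to the messiness of registry
data.

## Weight estimation choices

All treatment-process models are logistic regressions fitted on previously
untreated person-periods pooled across visits; once treatment has started
it continues with probability 1, so treated-history rows never enter a fit
and their weight factors are exactly 1.  The denominator conditions on the
current covariate ($A \sim L$, the correct model under the generator); the
numerators carry a separate intercept (and, when stabilizing on baseline
information, a separate $L$-slope) per visit, implemented as one pooled
model with a categorical visit factor.  For the IPACW numerator, the
baseline covariate of the trial replaces $L_0$, and the per-visit index is
the calendar visit at which deviation is at risk, pooled across trials;
the models are fitted on the *uncensored* stack so deviation visits
contribute their outcome.  Probabilities are floored at $10^{-12}$ before
ratio formation and any flooring is surfaced as a positivity warning.
Grouped cumulative weight products are computed in log space: a global
running product across thousands of individuals under- or overflows double
precision when single factors reach $10^{\pm 10}$ (strong-confounding
scenarios), while within-individual log sums stay moderate.

Optional weight truncation caps weights at a percentile of the pooled
weight distribution (default 95 when enabled).  The pooled — rather than
per-interval — distribution matches the single-percentile convention, and
the type-1 (inverse-CDF) quantile is used so that truncation is idempotent.

## Numerical choices in the Aalen fitter

At each event time the increment solves weighted least-squares normal
equations over the at-risk rows.  Risk-set cross-product matrices for all
event times are assembled from two reverse cumulative sums (rows with
$t_{stop} \ge t$ minus rows with $t_{start} \ge t$), making the fitter
$O(np^2 + \text{events}\,p^3)$.  Treatment-lag columns are identically
zero before their lag index and enter the design only at event times with
$\lfloor t \rfloor \ge j$; including them earlier would make the normal
equations singular by construction.  Genuinely singular increments are
skipped with the cumulative carried forward and counted in the
diagnostics (strict mode errors instead).  Negative fitted increments are
retained — clipping them would bias the cumulative coefficients — and only
the final survival value is clamped to $[0, 1]$, with a clamp count kept.
Cox ties use the Efron correction; simulated event times are continuous so
this matters only for user data.

## Problem sizes used by the shipped checks

The packaged verification uses cohorts of n = 5000 with 200 replicates per
scenario (the published study used 1000 — the Monte-Carlo tolerance scales
accordingly as $3\,\mathrm{SD}/\sqrt{n_{\text{reps}}}$), a 50 000-individual
cohort for parameter recovery, a one-million-individual randomized trial
for the truth fixture, and a reduced bootstrap-coverage study (100 cohorts
of n = 300 with B = 100) for interval calibration.  These sizes are the
package's choices for a desk-scale reproduction; `run_study()` accepts the
full published sizes unchanged.

## Known limitations and open edges

* The baseline treated fraction implied by the published scenario-1
  parameters is about 28%, while the accompanying description rounds it to
  25%; the package follows the parameters, not the rounding.
* The empirical between-replicate SDs of both estimators here are smaller
  (roughly half) than the published ones at identical means; the
  acceptance comparisons rest on the means.  A candidate explanation is a
  difference in how the original weight models were smoothed or pooled,
  which affects estimator variance but not consistency.
* Risk ratios, survival ratios and restricted-mean contrasts are one-line
  extensions of `risk_difference()` left unimplemented and untested.
* The heterogeneity test for a common treatment effect across trials uses
  a Wald statistic on trial-by-arm interactions with a model-based
  variance; with weighted data a robust variance would be preferable for
  formal inference (the package's bootstrap covers the estimands
  themselves).
* Eligibility is a washout on prior treatment only; covariate-availability
  predicates from registry-style protocols are out of scope.
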