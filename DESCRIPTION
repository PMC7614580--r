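Package: seqtrials
Title: Sequential Trial Emulation and Marginal Structural Models for
    Time-Varying Treatments and Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Causal inference for the effect of a sustained ("always" versus
    "never" treated) binary treatment strategy on a survival outcome using
    longitudinal observational data subject to time-dependent confounding.
    Implements two estimation approaches that target the same marginal risk
    difference: marginal structural models fitted with stabilized inverse
    probability of treatment weights (MSM-IPTW), and emulation of a sequence
    of target trials with artificial censoring at treatment deviation and
    inverse probability of artificial-censoring weights (IPACW).  Hazard
    models include the weighted Aalen additive-hazards model with
    time-varying cumulative coefficients and the weighted Cox model with a
    Breslow baseline.  Counterfactual survival curves and marginal risk
    differences are obtained by cloning-based empirical standardization, with
    nonparametric bootstrap confidence intervals.  Also provides a
    longitudinal data-generating mechanism with treatment-confounder
    feedback and a shared frailty, ground-truth computation via large
    simulated randomized trials, exact nonparametric estimators for the
    two-visit binary setting, and a simulation study runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
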