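#!/usr/bin/env Rscript
# Regenerates the cached ground-truth counterfactual survival fixture at
# inst/extdata/truth_scenario1.csv from a large simulated randomized trial
# (N = 1e6).  The truth does not depend on the treatment-assignment
# parameters, so the same fixture applies to all three scenario presets.
# Run from the repository root:  Rscript scripts/make_truth_fixture.R
library(seqtrials)
tr <- compute_truth(scenario_params("scenario1"), N = 1e6, seed = 20260101,
                    times = sort(unique(c(seq(0, 5, by = 0.05), 1:5))))
out <- file.path("inst", "extdata", "truth_scenario1.csv")
write.csv(as.data.frame(tr), out, row.names = FALSE)
cat("wrote", out, "N =", attr(tr, "N_truth"), "\n")
print(tr[tr$t %in% 1:5, ])
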