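#!/usr/bin/env Rscript
# Fit the mechanical parameters to the synthetic dataset by ABC rejection.
#
# A desk-scale run: 400 candidate simulations from the broad uniform priors
# (the full study design uses 10,000 acceptances; the sampler is the same).
# The acceptance threshold is calibrated so that roughly 12% of candidates
# are accepted, mirroring a tolerance chosen to keep only good fits.
#
# Outputs (results/):
#   abc_reference_table.csv  every candidate with its total error z
#   abc_posterior.csv        the accepted parameter sets
#   abc_fit_meta.json        threshold, acceptance rate, seed

library(epiboly)
library(jsonlite)
dir.create("results", showWarnings = FALSE)

n_sim <- 400
seed <- 7
grid <- sim_grid_centered(1500, 20)
ds <- read_dataset("results/synthetic_dataset")

message(sprintf("Evaluating %d prior draws (this is the long step) ...", n_sim))
tb <- abc_reference_table(ds$data, prior_spec(), grid, n_sim = n_sim,
                          seed = seed, progress = 50)
write.csv(tb, "results/abc_reference_table.csv", row.names = FALSE)

thr <- abc_threshold_quantile(tb, accept_fraction = 0.12)
post <- as_abc_posterior(tb, thr, priors = prior_spec(), seed = seed)
write_posterior(post, "results/abc_posterior.csv")
write_json(list(threshold = thr, n_sim = n_sim,
                n_accepted = nrow(post$samples),
                acceptance_rate = nrow(post$samples) / n_sim,
                rejections = as.list(table(tb$rejected_reason)),
                seed = seed),
           "results/abc_fit_meta.json", auto_unbox = TRUE, digits = NA)
message(sprintf("  threshold %.0f, accepted %d / %d (%.0f%%)",
                thr, nrow(post$samples), n_sim,
                100 * nrow(post$samples) / n_sim))
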