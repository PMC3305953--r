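#!/usr/bin/env Rscript
# Stage 2: MCMC calibration of the natural-history model.
# Fits the annual transition probabilities to the stage-specific incidence,
# mortality and prevalence targets from stage 1 by Metropolis-Hastings
# (3 chains), keeps the pooled post-burn-in posterior for the PSA, and the
# highest-likelihood sampled set for the base case.

library(crcscreen)

lt <- read_life_table("results/fixtures/life_table.csv")
targets <- read_targets("results/fixtures/calibration_targets.csv")
truth <- read_nh_params("results/fixtures/true_params.csv")

cal <- run_calibration(targets,
                       mcmc_config(n_chains = 3, burn_in = 500,
                                   n_samples = 1200, seed = 2),
                       lt, init = truth)

dir.create("results/calibration", showWarnings = FALSE, recursive = TRUE)
write.csv(cal$posterior, "results/calibration/posterior.csv", row.names = FALSE)
write_nh_params(cal$map_params, "results/calibration/map_params.csv")

cat(sprintf("Chains: %d, acceptance rates %s\n", 3,
            paste(sprintf("%.2f", cal$acceptance), collapse = ", ")))
cat(sprintf("Best log-likelihood: %.2f over %d pooled samples\n",
            max(cal$posterior$log_likelihood), nrow(cal$posterior)))
tv <- crcscreen:::params_to_vector(truth)
mv <- crcscreen:::params_to_vector(cal$map_params)
cat("Largest relative deviation of the MAP set from truth:",
    sprintf("%.1f%% (%s)\n", 100 * max(abs(mv - tv) / pmax(tv, 1e-6)),
            names(which.max(abs(mv - tv) / pmax(tv, 1e-6)))))
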