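#!/usr/bin/env Rscript
# Stage 3: base-case cost-effectiveness of the screening scenarios.
# Simulates no screening, the three core scenarios and the five age
# variants with the calibrated (MAP) natural-history set, then assembles
# the cost/QALY table with ICERs and the efficiency frontier, and the
# lifetime event-rate table (procedures, complications, detection routes).

library(crcscreen)

lt <- read_life_table("results/fixtures/life_table.csv")
params <- read_nh_params("results/calibration/map_params.csv")
values <- parameter_values()

ids <- strategy_presets()
res <- lapply(ids, function(id) simulate_strategy(id, params, lt, values))
names(res) <- ids

dir.create("results/basecase", showWarnings = FALSE, recursive = TRUE)
ce <- ce_table(res)
write.csv(ce, "results/basecase/ce_results.csv", row.names = FALSE)
write.csv(event_table(res), "results/basecase/event_rates.csv",
          row.names = FALSE)

none <- res$none
cat("Per-person discounted results (vs no screening):\n")
for (id in setdiff(ids, "none")) {
  ic <- compute_icer(res[[id]], none)
  cat(sprintf("  %-12s dCost %8.2f  dQALY %8.5f  ICER %9.0f  (%s)\n",
              id, ic$delta_cost, ic$delta_qaly, ic$icer, ic$note))
}
cat("\nEfficiency frontier:\n")
print(ce[, c("id", "cost", "qaly", "status", "frontier_icer")], digits = 5)
cat(sprintf("\nLifetime colonoscopies per 100,000: FIT %0.f vs gFOBT %0.f\n",
            res$FIT_55_74$tally["col_diagnostic"] +
              res$FIT_55_74$tally["col_surveillance"],
            res$gFOBT_55_74$tally["col_diagnostic"] +
              res$gFOBT_55_74$tally["col_surveillance"]))
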