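#!/usr/bin/env Rscript
# Stage 1: synthetic study inputs.
# Generates the Gompertz life table and the calibration target set (cancer
# incidence by stage and mortality in 5-year bands 50-84, adenoma and
# undiagnosed-cancer prevalence at 55/60/65, 5% observation CV) from the
# package's default "true" natural-history parameters, and writes them as
# CSVs for the later stages.

library(crcscreen)

out <- "results/fixtures"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

scenario <- synth_scenario(seed = 1)
paths <- write_fixtures(out, scenario)

gen <- generate_targets(scenario)
cat("Wrote", length(paths), "fixture files under", out, "\n")
cat(sprintf("Life table: q(30) = %.2e, q(70) = %.4f, q(100) = %.0f\n",
            q_other_at(gen$life_table, 30), q_other_at(gen$life_table, 70),
            q_other_at(gen$life_table, 100)))
cat(sprintf("Targets: %d observations (%s)\n", nrow(gen$targets),
            paste(names(table(gen$targets$quantity)), collapse = ", ")))
truth_run <- run_natural_history(gen$truth, gen$life_table)
cat(sprintf("Truth: lifetime incidence %.0f, mortality %.0f per 100,000; stage split %s\n",
            truth_run$lifetime$incidence_per_100k,
            truth_run$lifetime$mortality_per_100k,
            paste(sprintf("%.0f%%", 100 * truth_run$lifetime$stage_dist),
                  collapse = "/")))
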