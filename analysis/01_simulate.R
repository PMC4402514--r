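#!/usr/bin/env Rscript
# Generate the two synthetic cohorts used throughout the analysis:
#   results/sim/default    — standard conditions (600 internal exons,
#                            500 hill / 100 dip, constant hill delta +0.1)
#   results/sim/structural — tier-dependent hill deltas (low 0.15 / high 0.05)
#                            and a 6.5% hypomethylated prevalence
suppressPackageStartupMessages(library(exonmeth))

sim <- simulate_cohort(sim_config(seed = 1L), "results/sim/default")
cat(sprintf("default cohort: %d internal exons (%d hill, %d dip), genome %s bp\n",
            nrow(sim$truth), sum(sim$truth$class == "hill"),
            sum(sim$truth$class == "dip"),
            format(sim$seqlengths[[1]], big.mark = ",")))

sim2 <- simulate_cohort(
  sim_config(hill_delta_by_tier = c(low = 0.15, mid = 0.10, high = 0.05),
             dip_fraction = 0.065, seed = 3L),
  "results/sim/structural")
cat(sprintf("structural cohort: %d internal exons, %d dips (%.1f%%)\n",
            nrow(sim2$truth), sum(sim2$truth$class == "dip"),
            100 * mean(sim2$truth$class == "dip")))
cat("truth tables: results/sim/*/truth.tsv\n")
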