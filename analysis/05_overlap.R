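#!/usr/bin/env Rscript
# DNase-hotspot and predicted-enhancer overlap of the four exon sets on the
# default cohort, plus the end-to-end truth recovery report.
suppressPackageStartupMessages({library(exonmeth); library(jsonlite)})

dir <- "results/sim/default"
cfg <- run_config(
  gtf = file.path(dir, "annotation.gtf"),
  calls = file.path(dir, "cpg_calls.tsv"),
  genome = file.path(dir, "genome.fa"),
  fpkm = file.path(dir, "fpkm.tsv"),
  hotspots = file.path(dir, "dnase_hotspots.bed"),
  enhancers = file.path(dir, "enhancers.bed"),
  stages = c("annotations", "methylation", "expression", "stats", "overlap"),
  seed = 31L)
res <- suppressMessages(suppressWarnings(run_pipeline(cfg)))

ov <- res$overlap$summary
for (k in grep("fraction", names(ov), value = TRUE))
  cat(sprintf("%-32s %5.1f%%\n", k, 100 * ov[[k]]))

truth <- read.delim(file.path(dir, "truth.tsv"))
rec <- truth_recovery_report(truth, res$scores, res$expression,
                             res$overlap$hotspot_flags)
cat("\nconfusion matrix (programmed class vs called state):\n")
print(rec$confusion)
cat(sprintf("class accuracy %.3f | delta bias %+.4f | delta RMSE %.4f | tier accuracy %.3f\n",
            rec$accuracy, rec$delta_bias, rec$delta_rmse, rec$tier_accuracy))
write_json(c(ov, list(accuracy = rec$accuracy, delta_bias = rec$delta_bias,
                      delta_rmse = rec$delta_rmse)),
           "results/overlap.json", auto_unbox = TRUE, digits = 6,
           pretty = TRUE)
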