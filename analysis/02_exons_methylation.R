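#!/usr/bin/env Rscript
# Select the internal-exon universe from the default cohort's annotation and
# score regional methylation with the coupled-region correction; classify
# hills and dips at the 0.5 threshold.
suppressPackageStartupMessages(library(exonmeth))

tx <- load_transcripts("results/sim/default/annotation.gtf", "GTF")
exons <- select_internal_exons(tx, min_intron = 600L)
exons <- define_mid_intron_regions(exons)
est <- read.delim("results/sim/default/est_rates.tsv")
exons <- attach_est(exons, est)

calls <- read_cpg_calls("results/sim/default/cpg_calls.tsv")
scores <- score_triplets(exons, calls)

dir.create("results", showWarnings = FALSE)
write.table(as.data.frame(exons), "results/exons.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(scores, "results/methylation.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat(sprintf("scored %d exons: %d methylated, %d hypomethylated, %d unscored\n",
            nrow(scores), sum(scores$meth_class == "methylated"),
            sum(scores$meth_class == "hypomethylated"),
            sum(scores$meth_class == "unscored")))
cat(sprintf("%d triplets excluded by the coupled-region correction\n",
            sum(scores$excluded)))
comp <- scores[!scores$excluded, ]
st <- sign_test(comp$exon_score, comp$up_score, comp$down_score)
cat(sprintf("exon > both flanks in %d of %d informative triplets (p = %.3g, 1/3 null)\n",
            st$k, st$n, st$p_value))
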