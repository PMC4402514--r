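#!/usr/bin/env Rscript
# Expression tiers and the differential statistics: methylation-expression
# correlation (10,000 permutations), upstream/downstream delta correlation
# (1,000 permutations), tier rank-sum contrasts, quintile separation, GC
# deltas, gene thirds, and the gene-level hypo-exon expectation. The tier
# contrasts run on the structural cohort, whose hill deltas depend on tier.
suppressPackageStartupMessages({library(exonmeth); library(jsonlite)})

run_stats <- function(dir, seed) {
  tx <- load_transcripts(file.path(dir, "annotation.gtf"), "GTF")
  exons <- suppressMessages(select_internal_exons(tx))
  scores <- score_triplets(exons, read_cpg_calls(file.path(dir, "cpg_calls.tsv")))
  expr <- assign_expression(exons, tx, read_fpkm(file.path(dir, "fpkm.tsv")))
  comp <- scores[!scores$excluded, ]
  ei <- match(comp$exon_key, expr$exon_key)
  tier <- expr$tier[ei]
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  names(genome) <- sub("\\s.*", "", names(genome))
  gc <- composition_deltas(exons, genome)
  hypo <- comp$meth_class == "hypomethylated"
  gi <- match(comp$exon_key, gc$exon_key)
  si <- match(exons$exon_key, scores$exon_key)
  sp <- transcript_spans(tx)
  gene_sp <- do.call(rbind, lapply(split(sp, sp$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], span_start = min(d$span_start),
               span_end = max(d$span_end), strand = d$strand[1])))
  gm <- match(exons$gene_id, gene_sp$gene_id)
  thirds <- factor(assign_gene_third(exons$start, exons$end,
                                     gene_sp$span_start[gm],
                                     gene_sp$span_end[gm], exons$strand),
                   c("5prime", "middle", "3prime"))
  scored <- scores$meth_class[si] != "unscored"
  hypo_all <- scores$meth_class[si] == "hypomethylated"
  list(
    meth_expr = unclass(permutation_pearson(
      comp$exon_score, log(expr$exon_fpkm[ei]), 10000L, seed)),
    delta_updown = unclass(permutation_pearson(
      comp$delta_up, comp$delta_down, 1000L, seed)),
    delta_low_vs_high_p = rank_sum_compare(
      c(comp$delta_up[tier == "low20"], comp$delta_down[tier == "low20"]),
      c(comp$delta_up[tier == "high20"], comp$delta_down[tier == "high20"])),
    separation = as.list(set_separation(comp$exon_score[tier == "low20"],
                                        comp$exon_score[tier == "high20"])),
    gc_delta_hypo_vs_meth_p = list(
      up = rank_sum_compare(gc$d_gc_up[gi][hypo], gc$d_gc_up[gi][!hypo]),
      down = rank_sum_compare(gc$d_gc_down[gi][hypo], gc$d_gc_down[gi][!hypo])),
    thirds = thirds_enrichment(as.integer(table(thirds[scored & hypo_all])),
                               as.integer(table(thirds[scored]))),
    gene_level = within(gene_level_hypo_expectation(
      exons$gene_id[scored], hypo_all[scored], 200L, seed), rm(per_gene))
  )
}

out <- list(default = run_stats("results/sim/default", 11L),
            structural = run_stats("results/sim/structural", 12L))
write_json(out, "results/stats.json", auto_unbox = TRUE, digits = 6,
           pretty = TRUE)

s <- out$structural
cat(sprintf("methylation~log(FPKM): r = %.2f, permutation p = %.2g\n",
            s$meth_expr$r_observed, s$meth_expr$p_empirical))
cat(sprintf("up~down delta correlation: r = %.2f (p = %.2g)\n",
            s$delta_updown$r_observed, s$delta_updown$p_empirical))
cat(sprintf("deltas low vs high tier: rank-sum p = %.2g\n",
            s$delta_low_vs_high_p))
cat(sprintf("gene thirds chi-square p = %.2g; genes with a hypo exon: %d observed vs %.1f expected\n",
            s$thirds$p_value, s$gene_level$observed_genes,
            s$gene_level$expected_genes))
cat("full table: results/stats.json\n")
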