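#' Assemble a run configuration
#'
#' Input paths plus the analysis parameters, with defaults matching the
#' standard settings used throughout the package: 600-nt minimum introns,
#' 200-nt flanks, site coverage > 4, 0.5 methylation threshold, 20% tiers,
#' 10,000 permutations for the methylation-expression correlation and 1,000
#' for the delta-delta correlation, 18-bp H3 smoothing, 500-bp enhancer
#' half-window and a 2-kb TSS distance control.
#'
#' @param gtf,genome,calls,fpkm,est,tracks_dir,h3,hotspots,enhancers Input
#'   paths; set any to `NULL` to skip the stages that need them (`gtf` and
#'   `calls` are required).
#' @param out_dir Optional directory for per-stage TSVs and the JSON summary.
#' @param min_intron,flank,min_coverage,meth_threshold,tier_frac Numeric
#'   thresholds (see module functions).
#' @param n_perm_expr,n_perm_delta Permutation counts.
#' @param smoothing,enhancer_half_width,tss_min_distance Chromatin and
#'   overlap parameters.
#' @param stages Character subset of
#'   `c("annotations","methylation","expression","stats","chromatin","overlap")`.
#' @param seed Integer seed for every stochastic step.
#' @return List of class `run_config`.
#' @export
run_config <- function(gtf, calls, genome = NULL, fpkm = NULL, est = NULL,
                       tracks_dir = NULL, h3 = NULL, hotspots = NULL,
                       enhancers = NULL, out_dir = NULL,
                       min_intron = 600L, flank = 200L, min_coverage = 4L,
                       meth_threshold = 0.5, tier_frac = 0.2,
                       n_perm_expr = 10000L, n_perm_delta = 1000L,
                       smoothing = 18L, enhancer_half_width = 500L,
                       tss_min_distance = 2000L,
                       stages = c("annotations", "methylation", "expression",
                                  "stats", "chromatin", "overlap"),
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full exon-methylation analysis
#'
#' Executes annotations -> methylation -> expression -> stats -> chromatin ->
#' overlap on the configured inputs, returning every table and statistic and
#' (when `out_dir` is set) writing per-stage TSVs plus a JSON summary.
#' Stages whose inputs are absent, or that are not listed in
#' `config$stages`, are skipped; downstream stages degrade gracefully.
#'
#' @param config A [run_config()].
#' @return List of class `run_result`: `exons`, `scores`, `expression`,
#'   `stats`, `chromatin`, `overlap`, `summary` (flat named list of the
#'   headline numbers).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c("gtf", "calls"))
    if (is.null(config[[p]]) || !file.exists(config[[p]]))
      stop("required input missing: ", p)
  on_stage <- function(s) s %in% config$stages
  res <- list(summary = list(seed = config$seed))
  genome <- if (!is.null(config$genome))
    Biostrings::readDNAStringSet(config$genome) else NULL
  if (!is.null(genome)) names(genome) <- sub("\\s.*", "", names(genome))

  # --- annotations -----------------------------------------------------------
  tx <- load_transcripts(config$gtf, "GTF")
  exons <- select_internal_exons(tx, config$min_intron, config$flank)
  exons <- define_mid_intron_regions(exons)
  if (!is.null(config$est) && file.exists(config$est)) {
    est <- as.data.frame(data.table::fread(config$est))
    names(est) <- c("chrom", "start", "end", "strand", "rate")
    exons <- attach_est(exons, est)
  }
  sp <- transcript_spans(tx)
  gene_sp <- do.call(rbind, lapply(split(sp, sp$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
               strand = d$strand[1L], span_start = min(d$span_start),
               span_end = max(d$span_end), stringsAsFactors = FALSE)))
  gm <- match(exons$gene_id, gene_sp$gene_id)
  exons$gene_third <- assign_gene_third(
    exons$start, exons$end, gene_sp$span_start[gm], gene_sp$span_end[gm],
    exons$strand)
  if (!is.null(genome)) {
    tss_by_gene <- vapply(split(sp, sp$gene_id), function(d)
      if (d$strand[1L] == "+") min(d$tss) else max(d$tss), numeric(1L))
    gm2 <- match(gene_sp$gene_id, names(tss_by_gene))
    gene_sp$tata <- annotate_tata_promoter(
      unname(tss_by_gene[gm2]), gene_sp$strand, gene_sp$chrom, genome)
    exons$tata_promoter <- gene_sp$tata[match(exons$gene_id, gene_sp$gene_id)]
  }
  res$exons <- exons
  res$summary$n_exons <- nrow(exons)
  res$summary$n_genes <- length(unique(exons$gene_id))

  # --- methylation -----------------------------------------------------------
  if (on_stage("methylation")) {
    calls <- read_cpg_calls(config$calls)
    scores <- score_triplets(exons, calls, config$min_coverage,
                             config$meth_threshold)
    res$scores <- scores
    res$summary$n_complete_triplets <- sum(!scores$excluded)
    res$summary$n_methylated <- sum(scores$meth_class == "methylated")
    res$summary$n_hypomethylated <- sum(scores$meth_class == "hypomethylated")
  }

  # --- expression ------------------------------------------------------------
  if (on_stage("expression") && !is.null(config$fpkm) &&
      file.exists(config$fpkm)) {
    fpkm <- read_fpkm(config$fpkm)
    expr <- assign_expression(exons, tx, fpkm, config$tier_frac)
    res$expression <- expr
    res$summary$n_low20 <- sum(expr$tier == "low20")
    res$summary$n_high20 <- sum(expr$tier == "high20")
  }

  # --- stats -----------------------------------------------------------------
  if (on_stage("stats") && !is.null(res$scores)) {
    st <- list()
    comp <- res$scores[!res$scores$excluded, , drop = FALSE]
    st$sign_test <- sign_test(comp$exon_score, comp$up_score, comp$down_score)
    st$delta_corr <- permutation_pearson(comp$delta_up, comp$delta_down,
                                         config$n_perm_delta, config$seed)
    if (!is.null(res$expression)) {
      ei <- match(comp$exon_key, res$expression$exon_key)
      pos <- res$expression$exon_fpkm[ei] > 0
      st$meth_expr_corr <- permutation_pearson(
        comp$exon_score[pos], log(res$expression$exon_fpkm[ei][pos]),
        config$n_perm_expr, config$seed)
      tier <- res$expression$tier[ei]
      low_d <- c(comp$delta_up[tier == "low20"], comp$delta_down[tier == "low20"])
      high_d <- c(comp$delta_up[tier == "high20"], comp$delta_down[tier == "high20"])
      st$delta_tier_ranksum <- rank_sum_compare(low_d, high_d)
      st$delta_tier_ranksum_split <- c(
        up = rank_sum_compare(comp$delta_up[tier == "low20"],
                              comp$delta_up[tier == "high20"]),
        down = rank_sum_compare(comp$delta_down[tier == "low20"],
                                comp$delta_down[tier == "high20"]))
      st$separation <- set_separation(
        comp$exon_score[tier == "low20"], comp$exon_score[tier == "high20"])
    }
    if (!is.null(genome)) {
      gc <- composition_deltas(exons, genome)
      st$gc <- gc
      gi <- match(comp$exon_key, gc$exon_key)
      hypo <- comp$meth_class == "hypomethylated"
      if (any(hypo) && any(!hypo)) {
        st$gc_class_ranksum <- c(
          up = rank_sum_compare(gc$d_gc_up[gi][hypo], gc$d_gc_up[gi][!hypo]),
          down = rank_sum_compare(gc$d_gc_down[gi][hypo],
                                  gc$d_gc_down[gi][!hypo]))
      }
    }
    si <- match(exons$exon_key, res$scores$exon_key)
    hypo_all <- res$scores$meth_class[si] == "hypomethylated"
    scored <- res$scores$meth_class[si] != "unscored"
    st$gene_level <- gene_level_hypo_expectation(
      exons$gene_id[scored], hypo_all[scored], n_perm = 200L,
      seed = config$seed)
    thirds <- factor(exons$gene_third, c("5prime", "middle", "3prime"))
    all_counts <- as.integer(table(thirds[scored]))
    hypo_counts <- as.integer(table(thirds[scored & hypo_all]))
    if (all(all_counts > 0) && sum(hypo_counts) > 0)
      st$thirds <- thirds_enrichment(hypo_counts, all_counts)
    res$stats <- st
    res$summary$sign_test_k <- st$sign_test$k
    res$summary$sign_test_n <- st$sign_test$n
    res$summary$sign_test_p <- st$sign_test$p_value
    res$summary$delta_corr_r <- st$delta_corr$r_observed
    res$summary$delta_corr_p <- st$delta_corr$p_empirical
    if (!is.null(st$meth_expr_corr)) {
      res$summary$meth_expr_r <- st$meth_expr_corr$r_observed
      res$summary$meth_expr_p <- st$meth_expr_corr$p_empirical
      res$summary$delta_tier_ranksum_p <- st$delta_tier_ranksum
      res$summary$separation_low_below <- unname(st$separation["low_below"])
      res$summary$separation_high_above <- unname(st$separation["high_above"])
    }
    if (!is.null(st$thirds)) res$summary$thirds_p <- st$thirds$p_value
  }

  # --- chromatin -------------------------------------------------------------
  if (on_stage("chromatin") && !is.null(config$tracks_dir) &&
      dir.exists(config$tracks_dir) && !is.null(res$scores) &&
      !is.null(res$expression)) {
    res$chromatin <- chromatin_stage(exons, res$scores, res$expression,
                                     config, genome)
    if (!is.null(res$chromatin$signature))
      res$summary$highe_lowm_top_marks <- sum(
        apply(res$chromatin$signature$heatmap, 1L, which.max) ==
          which(colnames(res$chromatin$signature$heatmap) == "HighE_LowM"))
  }

  # --- overlap ---------------------------------------------------------------
  if (on_stage("overlap") && !is.null(config$hotspots) &&
      file.exists(config$hotspots) && !is.null(res$scores)) {
    res$overlap <- overlap_stage(exons, res$scores, res$expression, config)
    res$summary <- c(res$summary, res$overlap$summary)
  }

  if (!is.null(config$out_dir)) write_results(res, config)
  class(res) <- "run_result"
  res
}

exon_sets4 <- function(exons, scores, expression) {
  si <- match(exons$exon_key, scores$exon_key)
  ei <- match(exons$exon_key, expression$exon_key)
  cls <- scores$meth_class[si]
  tier <- expression$tier[ei]
  set <- rep(NA_character_, nrow(exons))
  set[tier == "low20" & cls == "methylated"] <- "LowE_HighM"
  set[tier == "low20" & cls == "hypomethylated"] <- "LowE_LowM"
  set[tier == "high20" & cls == "methylated"] <- "HighE_HighM"
  set[tier == "high20" & cls == "hypomethylated"] <- "HighE_LowM"
  set
}

chromatin_stage <- function(exons, scores, expression, config, genome) {
  tracks <- list.files(config$tracks_dir, pattern = "\\.(bedGraph|bg|wig)$",
                       full.names = TRUE)
  if (!length(tracks)) return(NULL)
  seql <- if (!is.null(genome))
    stats::setNames(Biostrings::width(genome), names(genome)) else NULL
  set <- exon_sets4(exons, scores, expression)
  sets <- c("LowE_HighM", "LowE_LowM", "HighE_HighM", "HighE_LowM")
  profiles <- list()
  for (tf in tracks) {
    mk <- sub("\\.(bedGraph|bg|wig)$", "", basename(tf))
    dialect <- if (grepl("\\.wig$", tf)) "wiggle" else "bedGraph"
    track <- load_signal(tf, dialect, seql)
    profiles[[mk]] <- lapply(stats::setNames(sets, sets), function(st)
      junction_profile(exons[!is.na(set) & set == st, , drop = FALSE], track,
                       config$flank, 100L))
  }
  out <- list(profiles = profiles, signature = signature_summary(profiles))
  if (!is.null(config$h3) && file.exists(config$h3) && !is.null(seql)) {
    rb <- as.data.frame(data.table::fread(config$h3, header = FALSE))
    reads <- data.frame(chrom = as.character(rb[[1L]]), pos = rb[[2L]],
                        strand = if (ncol(rb) >= 6L) as.character(rb[[6L]]) else "+")
    h3 <- h3_occupancy(reads, config$smoothing, seql)
    out$h3 <- lapply(stats::setNames(sets, sets), function(st) {
      sub <- exons[!is.na(set) & set == st, , drop = FALSE]
      if (!nrow(sub)) return(NULL)
      junction_profile(sub, h3, config$flank, 100L)
    })
  }
  out
}

overlap_stage <- function(exons, scores, expression, config) {
  hot <- read_bed_regions(config$hotspots)
  ov <- overlap_fraction(exons, hot)
  sc_ov <- per_exon_hotspot_score(exons, hot)
  out <- list(hotspot_flags = stats::setNames(ov$flags, exons$exon_key),
              hotspot_scores = stats::setNames(sc_ov, exons$exon_key),
              summary = list(hotspot_fraction_all = ov$fraction))
  if (!is.null(expression)) {
    set <- exon_sets4(exons, scores, expression)
    for (st in c("LowE_HighM", "LowE_LowM", "HighE_HighM", "HighE_LowM")) {
      sub <- !is.na(set) & set == st
      if (any(sub))
        out$summary[[paste0("hotspot_fraction_", st)]] <- mean(ov$flags[sub])
    }
    hm <- !is.na(set) & set == "HighE_HighM" & ov$flags
    hh <- !is.na(set) & set == "HighE_LowM" & ov$flags
    if (any(hm) && any(hh))
      out$summary$hotspot_score_ranksum_p <-
        rank_sum_compare(sc_ov[hh], sc_ov[hm])
  }
  if (!is.null(config$enhancers) && file.exists(config$enhancers)) {
    enh <- enhancer_windows(read_bed_regions(config$enhancers),
                            config$enhancer_half_width)
    eov <- overlap_fraction(exons, enh)
    out$enhancer_flags <- stats::setNames(eov$flags, exons$exon_key)
    out$summary$enhancer_fraction_all <- eov$fraction
    if (!is.null(expression)) {
      set <- exon_sets4(exons, scores, expression)
      for (st in c("LowE_HighM", "LowE_LowM", "HighE_HighM", "HighE_LowM")) {
        sub <- !is.na(set) & set == st
        if (any(sub))
          out$summary[[paste0("enhancer_fraction_", st)]] <- mean(eov$flags[sub])
      }
    }
  }
  out
}

write_results <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    data.table::fwrite(df, file.path(config$out_dir, name), sep = "\t")
  w(as.data.frame(res$exons), "exons.tsv")
  if (!is.null(res$scores)) w(res$scores, "methylation.tsv")
  if (!is.null(res$expression)) w(res$expression, "expression.tsv")
  if (!is.null(res$chromatin$signature)) {
    w(res$chromatin$signature$profile_summary, "signature_profiles.tsv")
    hm <- as.data.frame(res$chromatin$signature$heatmap)
    hm <- cbind(modification = rownames(hm), hm)
    w(hm, "signature_heatmap.tsv")
  }
  jsonlite::write_json(res$summary,
                       file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}
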