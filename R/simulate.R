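#' Simulation configuration for a synthetic exon-methylation cohort
#'
#' Defaults define the standard study conditions for this package: 120 genes
#' of 7 exons (5 internal each, 600 internal exons), 300-nt exons separated
#' by 800-nt introns, CpGs on a fixed-phase grid at 0.12 per bp (36 per exon,
#' 24 per 200-nt flank), Poisson read depth with mean 30 and Binomial
#' methylated-read sampling, log-normal gene expression, expression-tier
#' dependent baseline methylation, a +0.1 methylation "hill" at methylated
#' exons and a "dip" below 0.3 at a 1/6 fraction of exons, class/tier
#' dependent histone-track amplitudes, and DNase-hotspot / enhancer coverage
#' over 40% / 30% of the dip exons in the high expression tier.
#'
#' @param n_genes Number of genes (one transcript each, alternating strand).
#' @param exons_per_gene Exons per transcript (>= 4 so internal exons exist).
#' @param exon_length,intron_length,spacer Segment sizes in nt.
#' @param cpg_rate_exon,cpg_rate_intron CpG density per bp (grid-placed).
#' @param depth Mean sequencing depth (Poisson).
#' @param expression_meanlog,expression_sdlog Log-normal FPKM parameters.
#' @param tier_frac Expression tier fraction.
#' @param tier_baseline_meth Named baselines `c(low=, mid=, high=)` for
#'   flank/intron methylation by expression tier.
#' @param hill_delta Methylation elevation of hill exons above their flanks.
#' @param hill_delta_by_tier Optional named override `c(low=, mid=, high=)`.
#' @param dip_fraction Fraction of internal exons programmed as dips.
#' @param dip_mu_range Uniform range for dip exon methylation (must stay
#'   below 0.5).
#' @param missing_fraction Fraction of internal exons whose upstream flank is
#'   emitted at sub-threshold coverage (exercises the coupled-region
#'   correction).
#' @param alt_fraction Fraction of internal exons given an alternative EST
#'   inclusion rate (in \[0.2, 0.8\]); the rest are constitutive (rate 1).
#' @param gc_exon,gc_intron Base-composition GC levels.
#' @param marks Histone-mark track names; the last is the
#'   "H3K36me3-like" mark with the reversed class preference.
#' @param hist_base Baseline track intensity (Poisson mean).
#' @param hist_amp Optional amplitude matrix (marks x 4 sets:
#'   LowE_HighM, LowE_LowM, HighE_HighM, HighE_LowM).
#' @param hotspot_over_dip_fraction,enhancer_over_dip_fraction Programmed
#'   coverage of dip exons in the high tier.
#' @param h3_reads_per_kb,h3_dup_fraction H3 read-start density and injected
#'   duplicate fraction.
#' @param tracks Emit histone/H3 tracks (disable to speed up
#'   methylation-only studies).
#' @param seed Integer seed; fixed seed implies byte-identical output files.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 120L, exons_per_gene = 7L,
                       exon_length = 300L, intron_length = 800L,
                       spacer = 3000L,
                       cpg_rate_exon = 0.12, cpg_rate_intron = 0.12,
                       depth = 30,
                       expression_meanlog = 1, expression_sdlog = 1,
                       tier_frac = 0.2,
                       tier_baseline_meth = c(low = 0.60, mid = 0.72, high = 0.85),
                       hill_delta = 0.1, hill_delta_by_tier = NULL,
                       dip_fraction = 1 / 6,
                       dip_mu_range = c(0.15, 0.30),
                       missing_fraction = 0.02,
                       alt_fraction = 0.1,
                       gc_exon = 0.55, gc_intron = 0.40,
                       marks = c("markA", "markB", "markC", "markD",
                                 "H3K36me3like"),
                       hist_base = 1, hist_amp = NULL,
                       hotspot_over_dip_fraction = 0.4,
                       enhancer_over_dip_fraction = 0.3,
                       h3_reads_per_kb = 50, h3_dup_fraction = 0.1,
                       tracks = TRUE, seed = 1L) {
  cfg <- as.list(environment())
  if (exons_per_gene < 4L) stop("exons_per_gene must be >= 4")
  if (intron_length <= 600L) stop("intron_length must exceed 600")
  if (max(dip_mu_range) >= 0.5)
    stop("inconsistent config: dip methylation range reaches 0.5")
  if (any(tier_baseline_meth + hill_delta > 1))
    stop("inconsistent config: baseline + hill_delta exceeds 1")
  if (is.null(cfg$hist_amp)) cfg$hist_amp <- default_hist_amp(marks)
  class(cfg) <- "sim_config"
  cfg
}

default_hist_amp <- function(marks) {
  sets <- c("LowE_HighM", "LowE_LowM", "HighE_HighM", "HighE_LowM")
  amp <- matrix(rep(c(0.5, 1.0, 1.0, 3.0), each = length(marks)),
                nrow = length(marks), dimnames = list(marks, sets))
  # the K36-like mark prefers methylated exons at high expression
  amp[length(marks), ] <- c(0.5, 0.3, 3.0, 1.0)
  amp
}

grid_cpg_positions <- function(start, end, rate) {
  w <- end - start
  k <- max(1L, round(rate * w))
  start + as.integer(floor((seq_len(k) - 0.5) * w / k))
}

random_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Generate a ground-truthed synthetic cohort
#'
#' Emits a complete input bundle — genome FASTA, GTF annotation, per-CpG
#' bisulfite call table, transcript FPKM table, EST inclusion rates, per-mark
#' histone bedGraph tracks, H3 read-start BED, DNase-hotspot and enhancer
#' BEDs — plus a truth table keyed by internal-exon coordinates. The
#' generative model: flank/intron methylation at a tier-dependent baseline;
#' hill exons elevated by `hill_delta`; dip exons drawn uniformly from
#' `dip_mu_range`; site depth Poisson, methylated reads Binomial; histone
#' tracks are triangular bumps over exon +/- 200 bp with class/tier
#' amplitudes plus Poisson noise.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list: `paths` (named file paths), `truth`
#'   (data.frame), `config`, `seqlengths`.
#' @export
simulate_cohort <- function(config = sim_config(), out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  ng <- config$n_genes; ne <- config$exons_per_gene
  el <- config$exon_length; il <- config$intron_length
  gene_len <- ne * el + (ne - 1L) * il
  head_pad <- 2000L
  gene_starts <- head_pad + (seq_len(ng) - 1L) * (gene_len + config$spacer)
  L <- gene_starts[ng] + gene_len + head_pad
  chrom <- "chr1"

  # --- gene models -----------------------------------------------------------
  exon_offsets <- (seq_len(ne) - 1L) * (el + il)
  exons <- data.frame(
    gene = rep(seq_len(ng), each = ne),
    idx = rep(seq_len(ne), ng),
    start = rep(gene_starts, each = ne) + rep(exon_offsets, ng)
  )
  exons$end <- exons$start + el
  exons$strand <- ifelse(exons$gene %% 2L == 1L, "+", "-")
  exons$gene_id <- sprintf("g%03d", exons$gene)
  exons$transcript_id <- paste0(exons$gene_id, ".t1")
  internal <- exons$idx > 1L & exons$idx < ne
  tru <- exons[internal, , drop = FALSE]
  n_int <- nrow(tru)
  tru$exon_key <- exon_key(chrom, tru$start, tru$end, tru$strand)

  # --- expression and tiers --------------------------------------------------
  gene_fpkm <- stats::rlnorm(ng, config$expression_meanlog,
                             config$expression_sdlog)
  tru$fpkm <- gene_fpkm[tru$gene]
  tier20 <- percentile_tiers(tru$exon_key, tru$fpkm, config$tier_frac)
  tru$tier <- c(low20 = "low", high20 = "high", other = "mid",
                zero = "mid")[tier20]

  # --- methylation classes ---------------------------------------------------
  n_dip <- round(config$dip_fraction * n_int)
  dip_idx <- sample.int(n_int, n_dip)
  tru$class <- "hill"; tru$class[dip_idx] <- "dip"
  tru$baseline_mu <- unname(config$tier_baseline_meth[tru$tier])
  delta <- if (!is.null(config$hill_delta_by_tier))
    unname(config$hill_delta_by_tier[tru$tier]) else
    rep(config$hill_delta, n_int)
  tru$exon_mu <- pmin(tru$baseline_mu + delta, 0.99)
  tru$exon_mu[dip_idx] <- stats::runif(n_dip, config$dip_mu_range[1L],
                                       config$dip_mu_range[2L])
  tru$programmed_delta <- tru$exon_mu - tru$baseline_mu
  tru$missing_flank <- FALSE
  if (config$missing_fraction > 0) {
    nm <- round(config$missing_fraction * n_int)
    if (nm > 0L) tru$missing_flank[sample.int(n_int, nm)] <- TRUE
  }

  # --- EST rates -------------------------------------------------------------
  tru$est_rate <- 1
  n_alt <- round(config$alt_fraction * n_int)
  if (n_alt > 0L) {
    ai <- sample.int(n_int, n_alt)
    tru$est_rate[ai] <- stats::runif(n_alt, 0.2, 0.8)
  }

  # --- hotspots / enhancers over dip exons in the high tier ------------------
  dip_high <- which(tru$class == "dip" & tru$tier == "high")
  tru$hotspot_covered <- FALSE
  tru$enhancer_covered <- FALSE
  k_hot <- round(config$hotspot_over_dip_fraction * length(dip_high))
  k_enh <- round(config$enhancer_over_dip_fraction * length(dip_high))
  if (k_hot > 0L) tru$hotspot_covered[sample(dip_high, k_hot)] <- TRUE
  if (k_enh > 0L) tru$enhancer_covered[sample(dip_high, k_enh)] <- TRUE

  # --- CpG grid and genome ---------------------------------------------------
  region_list <- lapply(seq_len(n_int), function(i) {
    s <- tru$start[i]; e <- tru$end[i]
    mid_off <- floor((il - 200L) / 2)
    # the sub-coverage flank (when programmed) is the transcriptionally
    # upstream one: genomic left on +, genomic right on -
    up_region <- if (tru$strand[i] == "+") "left" else "right"
    reg <- c("exon", "left", "right", "mid_left", "mid_right")
    data.frame(
      region = reg,
      start = c(s, s - 200L, e, s - il + mid_off, e + mid_off),
      end = c(e, s, e + 200L, s - il + mid_off + 200L, e + mid_off + 200L),
      mu = c(tru$exon_mu[i], rep(tru$baseline_mu[i], 4L)),
      low_cov = tru$missing_flank[i] & reg == up_region,
      stringsAsFactors = FALSE
    )
  })
  regions <- do.call(rbind, region_list)

  genome_chars <- random_bases(L, config$gc_intron)
  for (i in seq_len(nrow(exons)))
    genome_chars[(exons$start[i] + 1L):exons$end[i]] <-
      random_bases(el, config$gc_exon)

  cpg_pos <- lapply(seq_len(nrow(regions)), function(i) {
    rate <- if (regions$region[i] == "exon") config$cpg_rate_exon else
      config$cpg_rate_intron
    grid_cpg_positions(regions$start[i], regions$end[i], rate)
  })
  all_pos <- unlist(cpg_pos)
  genome_chars[all_pos + 1L] <- "C"
  genome_chars[all_pos + 2L] <- "G"

  # --- bisulfite calls -------------------------------------------------------
  n_per_region <- lengths(cpg_pos)
  mu_site <- rep(regions$mu, n_per_region)
  low_site <- rep(regions$low_cov, n_per_region)
  total <- stats::rpois(length(all_pos), config$depth)
  total[low_site] <- 3L
  meth <- stats::rbinom(length(all_pos), total, mu_site)
  calls <- data.frame(chrom = chrom, pos = all_pos, meth_reads = meth,
                      total_reads = total)
  calls <- calls[order(calls$pos), , drop = FALSE]
  calls <- calls[!duplicated(calls$pos), , drop = FALSE]

  # --- write files -----------------------------------------------------------
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    gtf = file.path(out_dir, "annotation.gtf"),
    calls = file.path(out_dir, "cpg_calls.tsv"),
    fpkm = file.path(out_dir, "fpkm.tsv"),
    est = file.path(out_dir, "est_rates.tsv"),
    h3 = file.path(out_dir, "h3_reads.bed"),
    hotspots = file.path(out_dir, "dnase_hotspots.bed"),
    enhancers = file.path(out_dir, "enhancers.bed"),
    truth = file.path(out_dir, "truth.tsv")
  )

  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- chrom
  Biostrings::writeXStringSet(genome, paths$genome)

  gtf <- sprintf(
    '%s\tsim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    chrom, exons$start + 1L, exons$end, exons$strand, exons$gene_id,
    exons$transcript_id)
  writeLines(gtf, paths$gtf)

  data.table::fwrite(calls, paths$calls, sep = "\t")
  data.table::fwrite(
    data.frame(transcript_id = paste0(sprintf("g%03d", seq_len(ng)), ".t1"),
               fpkm = gene_fpkm),
    paths$fpkm, sep = "\t")
  data.table::fwrite(
    data.frame(chrom = chrom, start = tru$start, end = tru$end,
               strand = tru$strand, rate = tru$est_rate),
    paths$est, sep = "\t")

  hot <- tru[tru$hotspot_covered, , drop = FALSE]
  data.table::fwrite(
    data.frame(chrom = rep(chrom, nrow(hot)), start = hot$start - 50L,
               end = hot$end + 50L, name = sprintf("hs%d", seq_len(nrow(hot))),
               score = round(stats::runif(nrow(hot), 15, 25), 2)),
    paths$hotspots, sep = "\t", col.names = FALSE)
  enh <- tru[tru$enhancer_covered, , drop = FALSE]
  enh_mid <- floor((enh$start + enh$end) / 2)
  data.table::fwrite(
    data.frame(chrom = rep(chrom, nrow(enh)), start = enh_mid,
               end = enh_mid + 1L, name = sprintf("enh%d", seq_len(nrow(enh))),
               score = rep(0L, nrow(enh))),
    paths$enhancers, sep = "\t", col.names = FALSE)

  if (config$tracks) {
    dir.create(file.path(out_dir, "tracks"), showWarnings = FALSE)
    set4 <- paste0(ifelse(tru$tier == "high", "HighE",
                          ifelse(tru$tier == "low", "LowE", "MidE")),
                   "_", ifelse(tru$class == "dip", "LowM", "HighM"))
    amp4 <- config$hist_amp
    for (mk in config$marks) {
      rows <- vector("list", n_int)
      for (i in seq_len(n_int)) {
        ws <- tru$start[i] - 200L; we <- tru$end[i] + 200L
        pos <- ws:(we - 1L)
        center <- (ws + we - 1L) / 2
        half <- (we - ws) / 2
        tri <- pmax(0, 1 - abs(pos - center) / half)
        a <- amp_for(amp4[mk, ], set4[i], tru$tier[i], tru$class[i])
        lam <- config$hist_base + a * tri
        rows[[i]] <- data.frame(chrom = chrom, start = pos, end = pos + 1L,
                                value = stats::rpois(length(pos), lam))
      }
      paths[[paste0("track_", mk)]] <-
        file.path(out_dir, "tracks", paste0(mk, ".bedGraph"))
      data.table::fwrite(do.call(rbind, rows), paths[[paste0("track_", mk)]],
                         sep = "\t", col.names = FALSE)
    }
    n_reads <- round(L / 1000 * config$h3_reads_per_kb)
    rp <- sample.int(L - 1L, n_reads, replace = TRUE) - 1L
    rs <- sample(c("+", "-"), n_reads, replace = TRUE)
    n_dup <- round(config$h3_dup_fraction * n_reads)
    if (n_dup > 0L) {
      di <- sample.int(n_reads, n_dup)
      rp <- c(rp, rp[di]); rs <- c(rs, rs[di])
    }
    data.table::fwrite(
      data.frame(chrom = chrom, start = rp, end = rp + 1L,
                 name = ".", score = 0L, strand = rs),
      paths$h3, sep = "\t", col.names = FALSE)
  }

  truth <- tru[, c("exon_key", "gene_id", "start", "end", "strand", "class",
                   "tier", "baseline_mu", "exon_mu", "programmed_delta",
                   "fpkm", "est_rate", "missing_flank", "hotspot_covered",
                   "enhancer_covered")]
  rownames(truth) <- NULL
  data.table::fwrite(truth, paths$truth, sep = "\t")

  invisible(list(paths = paths, truth = truth, config = config,
                 seqlengths = stats::setNames(L, chrom)))
}

amp_for <- function(amp_row, set4, tier, class) {
  if (tier %in% c("low", "high")) return(unname(amp_row[set4]))
  # mid tier: average the two tiers for the exon's class
  cls <- if (class == "dip") "LowM" else "HighM"
  mean(amp_row[paste0(c("LowE", "HighE"), "_", cls)])
}

#' Compare pipeline output against the programmed truth
#'
#' @param truth Truth table from [simulate_cohort()].
#' @param scores `triplet_scores` from [score_triplets()].
#' @param expression Optional expression assignment (for tier recovery).
#' @param hotspot_flags Optional named logical vector (exon_key ->
#'   overlapping) for hotspot recovery.
#' @return List: `confusion` (class x meth_class table), `accuracy` (on
#'   scored exons), `delta_bias`, `delta_rmse` (complete triplets),
#'   `tier_accuracy`, `hotspot_accuracy` where inputs allow.
#' @export
truth_recovery_report <- function(truth, scores, expression = NULL,
                                  hotspot_flags = NULL) {
  m <- match(truth$exon_key, scores$exon_key)
  if (anyNA(m))
    stop("truth keys missing from scores: ",
         paste(utils::head(truth$exon_key[is.na(m)], 5L), collapse = ", "))
  sc <- scores[m, , drop = FALSE]
  confusion <- table(programmed = truth$class, called = sc$meth_class)
  scored <- sc$meth_class != "unscored"
  want <- ifelse(truth$class == "dip", "hypomethylated", "methylated")
  accuracy <- mean(want[scored] == sc$meth_class[scored])
  comp <- !sc$excluded
  rec_delta <- (sc$delta_up + sc$delta_down) / 2
  resid <- rec_delta[comp] - truth$programmed_delta[comp]
  out <- list(confusion = confusion, accuracy = accuracy,
              n_scored = sum(scored), n_complete = sum(comp),
              delta_bias = mean(resid),
              delta_rmse = sqrt(mean(resid^2)))
  if (!is.null(expression)) {
    me <- match(truth$exon_key, expression$exon_key)
    tier_want <- c(low = "low20", mid = "other", high = "high20")[truth$tier]
    out$tier_accuracy <- mean(tier_want == expression$tier[me], na.rm = TRUE)
  }
  if (!is.null(hotspot_flags)) {
    mh <- hotspot_flags[truth$exon_key]
    out$hotspot_accuracy <- mean(mh == truth$hotspot_covered, na.rm = TRUE)
  }
  out
}
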