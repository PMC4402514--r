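# In-code fixture builders shared across the suite.

# Build an exon_triplets table directly (bypassing annotation selection) for
# unit tests of scoring, profiling and overlap.
tri_df <- function(start, end, strand = "+", chrom = "chr1", flank = 200L,
                   gene_id = "g1", intron = 1000L) {
  n <- max(length(start), length(end))
  start <- rep_len(start, n); end <- rep_len(end, n)
  strand <- rep_len(strand, n); chrom <- rep_len(chrom, n)
  gene_id <- rep_len(gene_id, n)
  plus <- strand == "+"
  df <- data.frame(
    exon_key = sprintf("%s:%d-%d:%s", chrom, start, end, strand),
    chrom = chrom, start = start, end = end, strand = strand,
    gene_id = gene_id,
    flank_up_start = ifelse(plus, start - flank, end),
    flank_up_end = ifelse(plus, start, end + flank),
    flank_down_start = ifelse(plus, end, start - flank),
    flank_down_end = ifelse(plus, end + flank, start),
    intron_up = intron, intron_down = intron,
    mid_up_start = NA_integer_, mid_up_end = NA_integer_,
    mid_down_start = NA_integer_, mid_down_end = NA_integer_,
    est_class = "other", est_inclusion = NA_real_,
    tata_promoter = NA, gene_third = NA_character_,
    stringsAsFactors = FALSE
  )
  class(df) <- c("exon_triplets", "data.frame")
  df
}

# Write a minimal GTF from an exon-level table with 0-based half-open coords.
write_toy_gtf <- function(exons, path = tempfile(fileext = ".gtf")) {
  writeLines(sprintf(
    '%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    exons$chrom, exons$start + 1L, exons$end, exons$strand,
    exons$gene_id, exons$transcript_id), path)
  path
}

# A transcript_models table built in code (already validated shape).
toy_tx <- function(exons) {
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  exons$exon_rank <- stats::ave(exons$start, exons$transcript_id,
                                FUN = seq_along)
  rownames(exons) <- NULL
  class(exons) <- c("transcript_models", "data.frame")
  exons
}

# Call table helper: one row per site.
toy_calls <- function(pos, meth, total, chrom = "chr1") {
  data.frame(chrom = chrom, pos = pos, meth_reads = meth, total_reads = total)
}

# A signal_track from a plain numeric vector (NA = masked).
toy_track <- function(v, chrom = "chr1") signal_track(stats::setNames(list(v), chrom))

# Small cached simulation shared by tests that only need a generic cohort.
local_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "exonmeth-shared-sim")
      cache <<- simulate_cohort(
        sim_config(n_genes = 24L, tracks = FALSE, seed = 11L), dir)
    }
    cache
  }
})
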