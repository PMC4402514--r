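#' Read a transcript FPKM table
#'
#' @param path TSV with columns `transcript_id`, `fpkm`.
#' @return data.frame with those two columns.
#' @export
read_fpkm <- function(path) {
  dt <- data.table::fread(path, header = "auto")
  data.table::setnames(dt, c("transcript_id", "fpkm"))
  fpkm <- as.data.frame(dt)
  fpkm$transcript_id <- as.character(fpkm$transcript_id)
  if (any(fpkm$fpkm < 0)) stop("negative FPKM in expression table")
  fpkm
}

#' Exon-level expression score
#'
#' Sums the FPKM of every transcript that contains an exon with identical
#' coordinates (exact-coordinate membership, mirroring RefSeq-exon
#' semantics). Transcripts missing from the FPKM table contribute 0 with a
#' warning.
#'
#' @param triplets An `exon_triplets` table.
#' @param tx A `transcript_models` table.
#' @param fpkm FPKM table as from [read_fpkm()].
#' @return Numeric vector of exon FPKM, parallel to `triplets`.
#' @export
exon_expression <- function(triplets, tx, fpkm) {
  if (any(fpkm$fpkm < 0)) stop("negative FPKM")
  key_tx <- exon_key(tx$chrom, tx$start, tx$end, tx$strand)
  val <- fpkm$fpkm[match(tx$transcript_id, fpkm$transcript_id)]
  if (anyNA(val)) {
    missing_tx <- unique(tx$transcript_id[is.na(val)])
    warning(length(missing_tx),
            " transcript(s) absent from FPKM table contribute 0")
    val[is.na(val)] <- 0
  }
  # sum FPKM per exon key over containing transcripts (each tx counted once)
  first_per_tx <- !duplicated(paste(key_tx, tx$transcript_id))
  sums <- tapply(val[first_per_tx], key_tx[first_per_tx], sum)
  out <- as.numeric(sums[triplets$exon_key])
  out[is.na(out)] <- 0
  out
}

#' Gene-level expression score
#'
#' For each exon, the gene locus is the union span of the transcripts that
#' contain the exon; the gene expression score is the FPKM sum over all
#' transcripts (same chromosome and strand) whose span overlaps that locus by
#' at least 1 bp.
#'
#' @inheritParams exon_expression
#' @return Numeric vector of gene FPKM, parallel to `triplets`.
#' @export
gene_expression <- function(triplets, tx, fpkm) {
  sp <- transcript_spans(tx)
  sp$fpkm <- fpkm$fpkm[match(sp$transcript_id, fpkm$transcript_id)]
  sp$fpkm[is.na(sp$fpkm)] <- 0
  key_tx <- exon_key(tx$chrom, tx$start, tx$end, tx$strand)
  vapply(seq_len(nrow(triplets)), function(i) {
    containing <- unique(tx$transcript_id[key_tx == triplets$exon_key[i]])
    if (!length(containing)) return(0)
    csp <- sp[sp$transcript_id %in% containing, , drop = FALSE]
    locus_s <- min(csp$span_start); locus_e <- max(csp$span_end)
    hit <- sp$chrom == triplets$chrom[i] & sp$strand == triplets$strand[i] &
      sp$span_start < locus_e & sp$span_end > locus_s
    sum(sp$fpkm[hit])
  }, numeric(1L))
}

#' Exon inclusion rate from expression scores
#'
#' @param exon_fpkm,gene_fpkm Non-negative numeric vectors.
#' @return `exon_fpkm / gene_fpkm`, `NA` where `gene_fpkm == 0`; values are
#'   capped at 1 with a warning when numerical drift pushes the ratio above 1.
#' @export
inclusion_rate <- function(exon_fpkm, gene_fpkm) {
  if (any(exon_fpkm < 0) || any(gene_fpkm < 0)) stop("negative FPKM")
  r <- ifelse(gene_fpkm > 0, exon_fpkm / gene_fpkm, NA_real_)
  if (any(r > 1, na.rm = TRUE)) {
    warning("inclusion rate > 1 capped at 1")
    r <- pmin(r, 1)
  }
  r
}

#' Partition exons into expression tiers
#'
#' Exons with non-positive FPKM are labeled `zero` and excluded from tiering.
#' Among the rest, the bottom `floor(frac * n)` by FPKM are `low20`, the top
#' `floor(frac * n)` are `high20`, and the remainder `other`. Ties are broken
#' by stable exon-key order so the partition is deterministic.
#'
#' @param exon_key Character keys (used for tie-breaking).
#' @param exon_fpkm Numeric FPKM per exon.
#' @param frac Tier fraction, in (0, 0.5).
#' @return Character vector in `{low20, high20, other, zero}`.
#' @export
percentile_tiers <- function(exon_key, exon_fpkm, frac = 0.2) {
  stopifnot(frac > 0, frac < 0.5)
  tier <- rep("zero", length(exon_fpkm))
  pos <- which(exon_fpkm > 0)
  if (length(pos) < 10L) stop("fewer than 10 exons with positive FPKM")
  k <- floor(frac * length(pos))
  ord <- pos[order(exon_fpkm[pos], exon_key[pos])]
  tier[pos] <- "other"
  if (k > 0L) {
    tier[ord[seq_len(k)]] <- "low20"
    tier[ord[seq.int(length(ord) - k + 1L, length(ord))]] <- "high20"
  }
  tier
}

#' Full expression assignment for an exon set
#'
#' Convenience wrapper combining [exon_expression()], [gene_expression()],
#' [inclusion_rate()] and [percentile_tiers()].
#'
#' @inheritParams exon_expression
#' @param frac Tier fraction.
#' @return data.frame: `exon_key`, `exon_fpkm`, `gene_fpkm`, `inclusion`,
#'   `tier`.
#' @export
assign_expression <- function(triplets, tx, fpkm, frac = 0.2) {
  ef <- exon_expression(triplets, tx, fpkm)
  gf <- gene_expression(triplets, tx, fpkm)
  data.frame(
    exon_key = triplets$exon_key,
    exon_fpkm = ef, gene_fpkm = gf,
    inclusion = inclusion_rate(ef, gf),
    tier = percentile_tiers(triplets$exon_key, ef, frac),
    stringsAsFactors = FALSE
  )
}
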