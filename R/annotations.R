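#' Load transcript models from GTF or BED12
#'
#' Parses gene models into a flat exon-level table with coordinates normalized
#' to 0-based half-open intervals, the convention used throughout the package.
#' GTF exon rows (1-based inclusive) are converted at this boundary; BED12
#' blocks are already 0-based half-open.
#'
#' @param file Path to the annotation file.
#' @param dialect One of `"GTF"` or `"BED12"`. For BED12, `gene_id` falls back
#'   to the name column (BED carries no gene grouping).
#' @return A `data.frame` of class `transcript_models` with one row per exon:
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end` (0-based
#'   half-open), `exon_rank` (genomic order within the transcript).
#' @export
load_transcripts <- function(file, dialect = c("GTF", "BED12")) {
  dialect <- match.arg(dialect)
  if (dialect == "GTF") {
    gr <- rtracklayer::import(file, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon records in GTF: ", file)
    df <- data.frame(
      transcript_id = as.character(gr$transcript_id),
      gene_id       = as.character(gr$gene_id),
      chrom         = as.character(GenomicRanges::seqnames(gr)),
      strand        = as.character(GenomicRanges::strand(gr)),
      start         = GenomicRanges::start(gr) - 1L,
      end           = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(file, format = "bed")
    if (length(gr) == 0L) stop("no records in BED12: ", file)
    blocks <- gr$blocks
    if (is.null(blocks)) stop("BED input lacks block structure (need BED12)")
    n_blocks <- S4Vectors::elementNROWS(blocks)
    chrom_starts <- GenomicRanges::start(gr) - 1L  # 0-based chromStart
    ub <- unlist(blocks, use.names = FALSE)
    off <- rep(chrom_starts, n_blocks)
    df <- data.frame(
      transcript_id = rep(as.character(gr$name), n_blocks),
      gene_id       = rep(as.character(gr$name), n_blocks),
      chrom         = rep(as.character(GenomicRanges::seqnames(gr)), n_blocks),
      strand        = rep(as.character(GenomicRanges::strand(gr)), n_blocks),
      start         = off + IRanges::start(ub) - 1L,
      end           = off + IRanges::end(ub),
      stringsAsFactors = FALSE
    )
  }
  if (any(!df$strand %in% c("+", "-")))
    stop("unknown strand symbol in annotation: ",
         paste(unique(setdiff(df$strand, c("+", "-"))), collapse = ", "))
  if (any(df$start >= df$end)) stop("exon interval with start >= end")
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  df$exon_rank <- stats::ave(df$start, df$transcript_id,
                             FUN = function(x) seq_along(x))
  # exons within a transcript must be disjoint and sorted
  bad <- unlist(lapply(split(df, df$transcript_id), function(d) {
    n <- nrow(d)
    if (n > 1L && any(d$start[-1L] < d$end[-n])) d$transcript_id[1L] else NULL
  }))
  if (length(bad))
    stop("overlapping exon blocks within transcript(s): ",
         paste(bad, collapse = ", "))
  rownames(df) <- NULL
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Per-transcript summary (span, TSS, TES)
#'
#' @param tx A `transcript_models` table.
#' @return One row per transcript with `span_start`, `span_end`, `tss`, `tes`
#'   (0-based positions of the first/last transcribed base) and `n_exons`.
#' @export
transcript_spans <- function(tx) {
  sp <- do.call(rbind, lapply(split(as.data.frame(tx), tx$transcript_id),
    function(d) {
      s <- min(d$start); e <- max(d$end)
      plus <- d$strand[1L] == "+"
      data.frame(transcript_id = d$transcript_id[1L], gene_id = d$gene_id[1L],
                 chrom = d$chrom[1L], strand = d$strand[1L],
                 span_start = s, span_end = e,
                 tss = if (plus) s else e - 1L,
                 tes = if (plus) e - 1L else s,
                 n_exons = nrow(d), stringsAsFactors = FALSE)
    }))
  rownames(sp) <- NULL
  sp
}

exon_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, start, end, strand)
}

#' Select the analyzed internal-exon universe with 200-nt intronic flanks
#'
#' Internal exons are exons that are neither first nor last in any transcript
#' in which they appear (keyed by identical genomic coordinates). Retained
#' exons must be flanked on both sides by introns longer than `min_intron`
#' in every transcript context, and the analyzed region must not overlap any
#' annotated TSS or TES. Exons identical in coordinates across transcripts
#' are deduplicated; `gene_id` is taken from the first contributing
#' transcript.
#'
#' @param tx A `transcript_models` table.
#' @param min_intron Introns must be strictly longer than this (nt).
#' @param flank Flank width in nt (transcriptionally upstream/downstream).
#' @param filter_scope `"flanks"` tests the union flank_up + exon + flank_down
#'   against TSS/TES points; `"introns"` tests the full flanking introns.
#' @return A `data.frame` of class `exon_triplets`: one row per retained exon
#'   with its key, coordinates, oriented flank intervals, flanking-intron
#'   lengths and placeholders for downstream annotations.
#' @export
select_internal_exons <- function(tx, min_intron = 600L, flank = 200L,
                                  filter_scope = c("flanks", "introns")) {
  filter_scope <- match.arg(filter_scope)
  tx <- as.data.frame(tx)
  if (nrow(tx) == 0L) {
    warning("empty annotation: returning empty exon set")
    return(empty_triplets())
  }
  key_all <- exon_key(tx$chrom, tx$start, tx$end, tx$strand)

  per_tx <- split(seq_len(nrow(tx)), tx$transcript_id)
  terminal <- character(0)
  cand <- vector("list", length(per_tx))
  for (i in seq_along(per_tx)) {
    idx <- per_tx[[i]]
    d <- tx[idx, , drop = FALSE]
    n <- nrow(d)
    terminal <- c(terminal, key_all[idx[c(1L, n)]])
    if (n < 3L) next
    j <- 2L:(n - 1L)
    cand[[i]] <- data.frame(
      key = key_all[idx[j]],
      chrom = d$chrom[j], start = d$start[j], end = d$end[j],
      strand = d$strand[j], gene_id = d$gene_id[j],
      intron_left = d$start[j] - d$end[j - 1L],
      intron_right = d$start[j + 1L] - d$end[j],
      stringsAsFactors = FALSE
    )
  }
  cand <- do.call(rbind, cand)
  terminal <- unique(terminal)
  if (is.null(cand) || nrow(cand) == 0L) {
    warning("no internal exons found")
    return(empty_triplets())
  }

  n0 <- length(unique(cand$key))
  cand <- cand[!cand$key %in% terminal, , drop = FALSE]
  n_terminal <- n0 - length(unique(cand$key))

  # deduplicate: min intron length over every transcript context
  if (nrow(cand)) {
    agg_min <- function(v) tapply(v, cand$key, min)
    ord <- !duplicated(cand$key)
    ded <- cand[ord, c("key", "chrom", "start", "end", "strand", "gene_id")]
    il <- agg_min(cand$intron_left)[ded$key]
    ir <- agg_min(cand$intron_right)[ded$key]
    ded$intron_left <- as.integer(il)
    ded$intron_right <- as.integer(ir)
  } else ded <- cand

  keep <- ded$intron_left > min_intron & ded$intron_right > min_intron
  n_intron <- sum(!keep)
  ded <- ded[keep, , drop = FALSE]

  # TSS/TES point filter on the analyzed region
  sp <- transcript_spans(tx)
  pts <- data.frame(chrom = rep(sp$chrom, 2L), pos = c(sp$tss, sp$tes))
  if (nrow(ded)) {
    rs <- if (filter_scope == "flanks") ded$start - flank else ded$start - ded$intron_left
    re <- if (filter_scope == "flanks") ded$end + flank else ded$end + ded$intron_right
    reg <- GenomicRanges::GRanges(ded$chrom, IRanges::IRanges(rs + 1L, re))
    pgr <- GenomicRanges::GRanges(pts$chrom, IRanges::IRanges(pts$pos + 1L, pts$pos + 1L))
    hit <- GenomicRanges::countOverlaps(reg, pgr) > 0L
    n_tss <- sum(hit)
    ded <- ded[!hit, , drop = FALSE]
  } else n_tss <- 0L

  out <- build_triplets(ded, flank)
  message(sprintf(
    "internal-exon selection: %d candidates; removed %d terminal-in-some-transcript, %d short-intron, %d TSS/TES-overlap; retained %d",
    n0, n_terminal, n_intron, n_tss, nrow(out)))
  out
}

build_triplets <- function(ded, flank) {
  plus <- ded$strand == "+"
  left_s <- ded$start - flank; left_e <- ded$start
  right_s <- ded$end; right_e <- ded$end + flank
  out <- data.frame(
    exon_key = ded$key, chrom = ded$chrom,
    start = ded$start, end = ded$end, strand = ded$strand,
    gene_id = ded$gene_id,
    flank_up_start = ifelse(plus, left_s, right_s),
    flank_up_end = ifelse(plus, left_e, right_e),
    flank_down_start = ifelse(plus, right_s, left_s),
    flank_down_end = ifelse(plus, right_e, left_e),
    intron_up = ifelse(plus, ded$intron_left, ded$intron_right),
    intron_down = ifelse(plus, ded$intron_right, ded$intron_left),
    mid_up_start = rep(NA_integer_, nrow(ded)),
    mid_up_end = rep(NA_integer_, nrow(ded)),
    mid_down_start = rep(NA_integer_, nrow(ded)),
    mid_down_end = rep(NA_integer_, nrow(ded)),
    est_class = rep("other", nrow(ded)),
    est_inclusion = rep(NA_real_, nrow(ded)),
    tata_promoter = rep(NA, nrow(ded)),
    gene_third = rep(NA_character_, nrow(ded)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("exon_triplets", "data.frame")
  out
}

empty_triplets <- function() {
  build_triplets(data.frame(key = character(0), chrom = character(0),
                            start = integer(0), end = integer(0),
                            strand = character(0), gene_id = character(0),
                            intron_left = integer(0), intron_right = integer(0),
                            stringsAsFactors = FALSE)[0, ], 200L)
}

#' Classify exons by EST inclusion rate
#'
#' Inclusion rate 1 is constitutive; rates in \[0.05, 0.95\] are alternative;
#' anything else (including a missing rate) is "other".
#'
#' @param rate Numeric vector of EST inclusion rates in \[0,1\]; `NA` allowed.
#' @return Character vector: `"constitutive"`, `"alternative"` or `"other"`.
#' @export
classify_by_est <- function(rate) {
  ok <- is.na(rate) | (rate >= 0 & rate <= 1)
  if (!all(ok)) stop("EST inclusion rate outside [0,1]")
  out <- rep("other", length(rate))
  out[!is.na(rate) & rate == 1] <- "constitutive"
  out[!is.na(rate) & rate >= 0.05 & rate <= 0.95] <- "alternative"
  out
}

#' Attach EST inclusion rates and classes to an exon set
#'
#' @param triplets An `exon_triplets` table.
#' @param est A data.frame with columns `chrom,start,end,strand,rate`.
#' @return `triplets` with `est_inclusion` and `est_class` filled in.
#' @export
attach_est <- function(triplets, est) {
  key <- exon_key(est$chrom, est$start, est$end, est$strand)
  m <- match(triplets$exon_key, key)
  triplets$est_inclusion <- est$rate[m]
  triplets$est_class <- classify_by_est(triplets$est_inclusion)
  triplets
}

#' Scan a gene promoter for a canonical TATA element
#'
#' Looks for at least one TATAWAWR match (IUPAC: W = A/T, R = A/G) on the
#' sense orientation of the `window` bp transcriptionally upstream of the TSS
#' (reverse-complemented for minus-strand genes).
#'
#' @param tss 0-based TSS position(s).
#' @param strand `"+"` or `"-"`, recycled.
#' @param chrom Chromosome name(s), recycled.
#' @param genome A named `DNAStringSet` (one entry per chromosome).
#' @param window Upstream window size in bp.
#' @param both_strands Also scan the antisense orientation.
#' @return Logical vector.
#' @export
annotate_tata_promoter <- function(tss, strand, chrom, genome, window = 1000L,
                                   both_strands = FALSE) {
  n <- max(length(tss), length(strand), length(chrom))
  tss <- rep_len(tss, n); strand <- rep_len(strand, n)
  chrom <- rep_len(chrom, n)
  vapply(seq_len(n), function(i) {
    seq_len_i <- length(genome[[chrom[i]]])
    if (strand[i] == "+") {
      s <- tss[i] - window; e <- tss[i]
    } else {
      s <- tss[i] + 1L; e <- tss[i] + 1L + window
    }
    if (s < 0L || e > seq_len_i) {
      warning("promoter window truncated at contig edge (", chrom[i], ")")
      s <- max(s, 0L); e <- min(e, seq_len_i)
    }
    if (e <= s) return(FALSE)
    region <- Biostrings::subseq(genome[[chrom[i]]], s + 1L, e)
    if (strand[i] == "-") region <- Biostrings::reverseComplement(region)
    # fixed = "subject": IUPAC codes are interpreted in the pattern only, so
    # ambiguous subject bases (N) never satisfy the motif
    hit <- Biostrings::countPattern("TATAWAWR", region, fixed = "subject") > 0L
    if (!hit && both_strands)
      hit <- Biostrings::countPattern(
        "TATAWAWR", Biostrings::reverseComplement(region),
        fixed = "subject") > 0L
    hit
  }, logical(1L))
}

#' Assign exons to gene thirds
#'
#' The gene span is split into three equal-length genomic segments; each exon
#' goes to the segment containing its midpoint (half-open segments; a midpoint
#' exactly on a boundary goes to the genomically-downstream segment). Labels
#' follow transcription direction: the segment containing the TSS is "5prime".
#'
#' @param exon_start,exon_end 0-based half-open exon coordinates.
#' @param span_start,span_end Gene span, 0-based half-open.
#' @param strand `"+"` or `"-"`.
#' @return Character vector in `{5prime, middle, 3prime}`.
#' @export
assign_gene_third <- function(exon_start, exon_end, span_start, span_end, strand) {
  n <- max(length(exon_start), length(span_start))
  exon_start <- rep_len(exon_start, n); exon_end <- rep_len(exon_end, n)
  span_start <- rep_len(span_start, n); span_end <- rep_len(span_end, n)
  strand <- rep_len(strand, n)
  if (any(exon_start < span_start | exon_end > span_end))
    stop("exon outside gene span")
  mid <- (exon_start + exon_end) / 2
  L <- span_end - span_start
  seg <- pmin(floor((mid - span_start) * 3 / L), 2)
  labs <- c("5prime", "middle", "3prime")
  ifelse(strand == "+", labs[seg + 1L], labs[3L - seg])
}

#' Define mid-intron control regions
#'
#' Sets `mid_up` / `mid_down` to the central `width`-nt window of each
#' flanking intron, left-floored when the centering remainder is odd. Mid
#' regions are absent (NA) when the intron is not longer than `width + 400`,
#' so that they can never touch the 200-nt flanks.
#'
#' @param triplets An `exon_triplets` table (carries intron lengths).
#' @param width Mid-region width in nt.
#' @return `triplets` with the four `mid_*` columns filled where defined.
#' @export
define_mid_intron_regions <- function(triplets, width = 200L) {
  plus <- triplets$strand == "+"
  # genomic-left intron interval: [start - intron_left, start)
  il <- ifelse(plus, triplets$intron_up, triplets$intron_down)
  ir <- ifelse(plus, triplets$intron_down, triplets$intron_up)
  lmid_s <- triplets$start - il + floor((il - width) / 2)
  rmid_s <- triplets$end + floor((ir - width) / 2)
  l_ok <- il > width + 400L
  r_ok <- ir > width + 400L
  up_s <- ifelse(plus, lmid_s, rmid_s); up_ok <- ifelse(plus, l_ok, r_ok)
  dn_s <- ifelse(plus, rmid_s, lmid_s); dn_ok <- ifelse(plus, r_ok, l_ok)
  triplets$mid_up_start <- ifelse(up_ok, as.integer(up_s), NA_integer_)
  triplets$mid_up_end <- ifelse(up_ok, as.integer(up_s + width), NA_integer_)
  triplets$mid_down_start <- ifelse(dn_ok, as.integer(dn_s), NA_integer_)
  triplets$mid_down_end <- ifelse(dn_ok, as.integer(dn_s + width), NA_integer_)
  triplets
}
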