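#' Read a per-CpG bisulfite call table
#'
#' Expected columns (TSV, with or without header): `chrom`, `pos` (0-based),
#' `meth_reads`, `total_reads`. Calls are taken as given per position; no
#' strand merging is applied (see `merge_cpg_strands`).
#'
#' @param path Path to the TSV.
#' @return data.frame with the four columns above.
#' @export
read_cpg_calls <- function(path) {
  dt <- data.table::fread(path, header = "auto")
  data.table::setnames(dt, c("chrom", "pos", "meth_reads", "total_reads"))
  calls <- as.data.frame(dt)
  calls$chrom <- as.character(calls$chrom)
  validate_calls(calls)
  calls
}

validate_calls <- function(calls) {
  if (any(calls$meth_reads > calls$total_reads))
    stop("meth_reads exceeds total_reads in call table")
  if (any(calls$meth_reads < 0L | calls$total_reads < 0L))
    stop("negative read counts in call table")
  invisible(calls)
}

#' Merge strand-paired CpG calls
#'
#' Sums read counts of calls at `pos` and `pos + 1` (the + and - strand
#' cytosines of one CpG), reporting the merged call at the + strand position.
#'
#' @param calls Call table as from [read_cpg_calls()].
#' @return Merged call table.
#' @export
merge_cpg_strands <- function(calls) {
  key <- paste(calls$chrom, calls$pos)
  partner <- paste(calls$chrom, calls$pos - 1L)
  is_minus <- partner %in% key
  shifted <- calls
  shifted$pos <- ifelse(is_minus, calls$pos - 1L, calls$pos)
  agg <- stats::aggregate(cbind(meth_reads, total_reads) ~ chrom + pos,
                          data = shifted, FUN = sum)
  agg[order(agg$chrom, agg$pos), , drop = FALSE]
}

#' Site-level methylation rate under a coverage filter
#'
#' A site qualifies only with read coverage strictly greater than
#' `min_coverage` (default: coverage > 4, i.e. at least 5 reads); otherwise
#' its rate is missing (`NA`).
#'
#' @param meth_reads,total_reads Non-negative integer vectors.
#' @param min_coverage Exclusive coverage threshold.
#' @return Numeric vector of methylation rates with `NA` for unqualified sites.
#' @export
site_methylation <- function(meth_reads, total_reads, min_coverage = 4L) {
  if (any(meth_reads > total_reads)) stop("meth_reads exceeds total_reads")
  ifelse(total_reads > min_coverage, meth_reads / total_reads, NA_real_)
}

#' Regional methylation scores
#'
#' Unweighted mean of qualifying site-level rates over each region; a region
#' with no qualifying CpG is missing (`NA`) with `n_sites = 0`.
#'
#' @param chrom,start,end Parallel vectors of regions (0-based half-open).
#' @param calls Call table.
#' @param min_coverage Exclusive coverage threshold passed to
#'   [site_methylation()].
#' @return data.frame with `value` and `n_sites` per region, in input order.
#' @export
regional_score <- function(chrom, start, end, calls, min_coverage = 4L) {
  n <- length(start)
  rate <- site_methylation(calls$meth_reads, calls$total_reads, min_coverage)
  ok <- !is.na(rate)
  out <- data.frame(value = rep(NA_real_, n), n_sites = integer(n))
  if (!any(ok) || n == 0L) return(out)
  sites <- GenomicRanges::GRanges(calls$chrom[ok],
                                  IRanges::IRanges(calls$pos[ok] + 1L,
                                                   calls$pos[ok] + 1L))
  regions <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(regions, sites)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    r <- rate[ok][S4Vectors::subjectHits(hits)]
    sums <- tapply(r, q, sum)
    cnts <- tapply(r, q, length)
    idx <- as.integer(names(sums))
    out$value[idx] <- as.numeric(sums) / as.numeric(cnts)
    out$n_sites[idx] <- as.integer(cnts)
  }
  out
}

#' Classify an exon's methylation state
#'
#' @param value Regional methylation scores (`NA` = missing).
#' @param threshold Scores strictly below are hypomethylated; at or above,
#'   methylated.
#' @return Character vector in `{hypomethylated, methylated, unscored}`.
#' @export
classify_methylation_state <- function(value, threshold = 0.5) {
  ifelse(is.na(value), "unscored",
         ifelse(value < threshold, "hypomethylated", "methylated"))
}

#' Score exon triplets with the coupled-region correction
#'
#' Computes exon / upstream-flank / downstream-flank regional scores for each
#' triplet (and mid-intron regions when defined). Triplets where any of the
#' three core regions is missing are flagged `excluded` (retained with their
#' partial scores) and receive no deltas; complete triplets get
#' `delta_up = exon - up` and `delta_down = exon - down`.
#'
#' @param triplets An `exon_triplets` table.
#' @param calls Call table.
#' @param min_coverage Exclusive site-coverage threshold.
#' @param threshold Methylation-class threshold.
#' @return data.frame of class `triplet_scores`, one row per triplet.
#' @export
score_triplets <- function(triplets, calls, min_coverage = 4L, threshold = 0.5) {
  sc <- function(s, e) {
    use <- !is.na(s)
    res <- data.frame(value = rep(NA_real_, nrow(triplets)),
                      n_sites = rep(NA_integer_, nrow(triplets)))
    if (any(use)) {
      r <- regional_score(triplets$chrom[use], s[use], e[use], calls,
                          min_coverage)
      res$value[use] <- r$value
      res$n_sites[use] <- r$n_sites
    }
    res
  }
  ex <- sc(triplets$start, triplets$end)
  up <- sc(triplets$flank_up_start, triplets$flank_up_end)
  dn <- sc(triplets$flank_down_start, triplets$flank_down_end)
  mu <- sc(triplets$mid_up_start, triplets$mid_up_end)
  md <- sc(triplets$mid_down_start, triplets$mid_down_end)
  complete <- !is.na(ex$value) & !is.na(up$value) & !is.na(dn$value)
  out <- data.frame(
    exon_key = triplets$exon_key,
    exon_score = ex$value, exon_n = ex$n_sites,
    up_score = up$value, up_n = up$n_sites,
    down_score = dn$value, down_n = dn$n_sites,
    mid_up_score = mu$value, mid_down_score = md$value,
    delta_up = ifelse(complete, ex$value - up$value, NA_real_),
    delta_down = ifelse(complete, ex$value - dn$value, NA_real_),
    meth_class = classify_methylation_state(ex$value, threshold),
    excluded = !complete,
    stringsAsFactors = FALSE
  )
  class(out) <- c("triplet_scores", "data.frame")
  out
}
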