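#' Read a BED interval file (3-6 columns) into a scored interval set
#'
#' Column 5 (score) is used when present. Coordinates stay 0-based half-open.
#'
#' @param path BED file.
#' @return data.frame sorted by (chrom, start): `chrom`, `start`, `end`,
#'   `score` (NA when absent).
#' @export
read_bed_regions <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), score = numeric(0)))
  dt <- as.data.frame(data.table::fread(path, header = FALSE))
  out <- data.frame(chrom = as.character(dt[[1L]]), start = dt[[2L]],
                    end = dt[[3L]],
                    score = if (ncol(dt) >= 5L) as.numeric(dt[[5L]]) else NA_real_,
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("BED interval with start >= end: ", path)
  out[order(out$chrom, out$start), , drop = FALSE]
}

regions_gr <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1L, regions$end))
}

#' Fraction of exons overlapping a region set
#'
#' An exon counts as overlapping when its body (flanks excluded) shares at
#' least 1 bp with any region; half-open semantics, so abutment is not
#' overlap.
#'
#' @param triplets An `exon_triplets` table (non-empty).
#' @param regions Interval set as from [read_bed_regions()].
#' @return List: `fraction`, and logical `flags` parallel to `triplets`.
#' @export
overlap_fraction <- function(triplets, regions) {
  if (!nrow(triplets)) stop("empty exon set")
  ex <- GenomicRanges::GRanges(triplets$chrom,
                               IRanges::IRanges(triplets$start + 1L,
                                                triplets$end))
  flags <- GenomicRanges::countOverlaps(ex, regions_gr(regions)) > 0L
  list(fraction = mean(flags), flags = flags)
}

#' Per-exon hotspot score
#'
#' Aggregates the scores of all regions overlapping each exon body
#' (`max` by default, or `mean`); exons overlapping nothing get `NA`.
#'
#' @param triplets An `exon_triplets` table.
#' @param regions Scored interval set.
#' @param agg `"max"` or `"mean"`.
#' @return Numeric vector parallel to `triplets`.
#' @export
per_exon_hotspot_score <- function(triplets, regions, agg = c("max", "mean")) {
  agg <- match.arg(agg)
  ex <- GenomicRanges::GRanges(triplets$chrom,
                               IRanges::IRanges(triplets$start + 1L,
                                                triplets$end))
  hits <- GenomicRanges::findOverlaps(ex, regions_gr(regions))
  out <- rep(NA_real_, nrow(triplets))
  if (length(hits)) {
    sc <- regions$score[S4Vectors::subjectHits(hits)]
    fn <- if (agg == "max") max else mean
    agg_sc <- tapply(sc, S4Vectors::queryHits(hits), fn)
    out[as.integer(names(agg_sc))] <- as.numeric(agg_sc)
  }
  out
}

#' Expand enhancer calls to fixed windows
#'
#' Each call becomes midpoint +/- `half_width` (a 1-kb window by default).
#' Overlapping windows are retained, not merged; windows are clamped at
#' position 0 with a warning.
#'
#' @param calls data.frame with `chrom`, `start`, `end` (points may use
#'   `end = start + 1`), optional `score`.
#' @param half_width Half window size in bp.
#' @return Scored interval set (sorted).
#' @export
enhancer_windows <- function(calls, half_width = 500L) {
  mid <- floor((calls$start + calls$end) / 2)
  s <- mid - half_width
  if (any(s < 0L)) {
    warning(sum(s < 0L), " window(s) clamped at contig start")
    s <- pmax(s, 0L)
  }
  out <- data.frame(chrom = calls$chrom, start = as.integer(s),
                    end = as.integer(mid + half_width),
                    score = if ("score" %in% names(calls)) calls$score else NA_real_,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}
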