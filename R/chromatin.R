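#' Per-base signal track with a missing-data mask
#'
#' A `signal_track` stores one numeric vector per contig; index i holds the
#' value at 0-based position i - 1, with `NA` marking positions without data
#' (distinct from an explicit zero).
#'
#' @param values Named list of numeric vectors.
#' @return A `signal_track` object.
#' @export
signal_track <- function(values) {
  stopifnot(is.list(values), !is.null(names(values)))
  if (any(vapply(values, function(v) any(v < 0, na.rm = TRUE), logical(1L))))
    stop("negative values in signal track")
  structure(list(values = values), class = "signal_track")
}

#' Fetch track values over a 0-based half-open interval
#'
#' Positions outside the stored contig are returned as `NA` (masked).
#'
#' @param track A `signal_track`.
#' @param chrom Contig name.
#' @param start,end 0-based half-open bounds.
#' @return Numeric vector of length `end - start`.
#' @export
track_values <- function(track, chrom, start, end) {
  v <- track$values[[chrom]]
  n <- end - start
  out <- rep(NA_real_, n)
  if (is.null(v)) return(out)
  lo <- max(start, 0L); hi <- min(end, length(v))
  if (hi > lo) out[(lo - start + 1L):(hi - start)] <- v[(lo + 1L):hi]
  out
}

#' Load a bedGraph or wiggle track into per-base values
#'
#' Intervals are expanded to 1-bp resolution; positions not covered by any
#' interval are masked (`NA`), not zero. Overlapping intervals or negative
#' values are errors.
#'
#' @param path Track file.
#' @param dialect `"bedGraph"` or `"wiggle"`.
#' @param seqlengths Optional named integer vector of contig lengths (vectors
#'   are otherwise sized to the last covered base).
#' @return A `signal_track`.
#' @export
load_signal <- function(path, dialect = c("bedGraph", "wiggle"),
                        seqlengths = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "bedGraph") {
    dt <- data.table::fread(path, header = FALSE)
    df <- data.frame(chrom = as.character(dt[[1L]]), start = dt[[2L]],
                     end = dt[[3L]], score = as.numeric(dt[[4L]]),
                     stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "wig")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr), score = gr$score,
                     stringsAsFactors = FALSE)
  }
  if (any(df$score < 0)) stop("negative values in signal track: ", path)
  values <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    n <- nrow(d)
    if (n > 1L && any(d$start[-1L] < d$end[-n]))
      stop("overlapping intervals in signal track: ", path)
    L <- if (!is.null(seqlengths) && d$chrom[1L] %in% names(seqlengths))
      seqlengths[[d$chrom[1L]]] else max(d$end)
    v <- rep(NA_real_, L)
    w <- d$end - d$start
    v[sequence(w, from = d$start + 1L)] <- rep(d$score, w)
    v
  })
  signal_track(values)
}

#' Nucleosome (H3) occupancy from read starts
#'
#' Collapses duplicate reads (same position and strand: alignment start on +,
#' stop on -), counts deduplicated read positions per base, and smooths with
#' an 18-bp running mean. The even window is split 9 left / 8 right of the
#' focal base: position i averages raw values over \[i - 9, i + 8\].
#' Out-of-contig positions contribute zero, so mass is conserved away from
#' contig edges.
#'
#' @param reads data.frame with `chrom`, `pos` (0-based) and `strand`.
#' @param window Smoothing window width (bp).
#' @param seqlengths Named integer vector of contig lengths.
#' @return A `signal_track` (no masked positions).
#' @export
h3_occupancy <- function(reads, window = 18L, seqlengths) {
  left <- ceiling(window / 2)        # 9 for window 18
  right <- window - left - 1L        # 8
  values <- lapply(names(seqlengths), function(ch) {
    r <- reads[reads$chrom == ch, , drop = FALSE]
    L <- seqlengths[[ch]]
    raw <- numeric(L)
    if (nrow(r)) {
      dedup <- r[!duplicated(paste(r$pos, r$strand)), , drop = FALSE]
      tab <- table(dedup$pos)
      raw[as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
    cs <- cumsum(c(0, raw))
    i <- seq_len(L)
    lo <- pmax(i - left, 1L); hi <- pmin(i + right, L)
    (cs[hi + 1L] - cs[lo]) / window
  })
  names(values) <- names(seqlengths)
  signal_track(values)
}

junction_windows <- function(start, end, strand, flank = 200L, exonic = 100L) {
  # 0-based positions of the acceptor (intron->exon) and donor (exon->intron)
  # windows in transcription order, per exon
  if (strand == "+") {
    list(acceptor = seq.int(start - flank, start + exonic - 1L),
         donor = seq.int(end - exonic, end + flank - 1L))
  } else {
    list(acceptor = rev(seq.int(end - exonic, end + flank - 1L)),
         donor = rev(seq.int(start - flank, start + exonic - 1L)))
  }
}

#' Junction-anchored signal profile over an exon set
#'
#' For each exon, the acceptor window covers the 200 intronic nt upstream of
#' the intron-exon junction plus the first 100 exonic nt, and the donor
#' window the last 100 exonic nt plus the 200 intronic nt downstream of the
#' exon-intron junction, both in transcription orientation (windows of
#' minus-strand exons are positionally reversed). Exons shorter than
#' `exonic` nt are skipped; an exon with any masked position in a window is
#' dropped from that window's average only. Profiles are positionwise means
#' across retained exons.
#'
#' @param triplets An `exon_triplets` table.
#' @param track A `signal_track`.
#' @param flank,exonic Intronic / exonic sub-window widths (nt).
#' @return List of class `junction_profile`: `acceptor`, `donor` (length
#'   `flank + exonic` each), `n_acceptor`, `n_donor`, `n_exons_used`,
#'   `mean_density`.
#' @export
junction_profile <- function(triplets, track, flank = 200L, exonic = 100L) {
  use <- (triplets$end - triplets$start) >= exonic
  tri <- triplets[use, , drop = FALSE]
  if (!nrow(tri)) stop("no exons long enough for junction profiling")
  w <- flank + exonic
  acc <- matrix(NA_real_, nrow(tri), w)
  don <- matrix(NA_real_, nrow(tri), w)
  for (i in seq_len(nrow(tri))) {
    jw <- junction_windows(tri$start[i], tri$end[i], tri$strand[i], flank, exonic)
    v <- track$values[[tri$chrom[i]]]
    L <- if (is.null(v)) 0L else length(v)
    ok_a <- jw$acceptor >= 0L & jw$acceptor < L
    ok_d <- jw$donor >= 0L & jw$donor < L
    if (all(ok_a)) acc[i, ] <- v[jw$acceptor + 1L]
    if (all(ok_d)) don[i, ] <- v[jw$donor + 1L]
  }
  acc_ok <- stats::complete.cases(acc)
  don_ok <- stats::complete.cases(don)
  if (!any(acc_ok) && !any(don_ok))
    stop("no exon with complete data in either junction window")
  ap <- if (any(acc_ok)) colMeans(acc[acc_ok, , drop = FALSE]) else rep(NA_real_, w)
  dp <- if (any(don_ok)) colMeans(don[don_ok, , drop = FALSE]) else rep(NA_real_, w)
  structure(list(acceptor = ap, donor = dp,
                 n_acceptor = sum(acc_ok), n_donor = sum(don_ok),
                 n_exons_used = sum(acc_ok | don_ok),
                 mean_density = mean(c(ap, dp), na.rm = TRUE)),
            class = "junction_profile")
}

#' Max-normalize mean densities across exon sets
#'
#' Divides each modification row by its maximum over the exon sets, so every
#' row maximum becomes exactly 1. All-zero rows stay zero with a warning.
#'
#' @param means Numeric matrix, modifications x exon sets.
#' @return Matrix of the same shape.
#' @export
normalize_across_sets <- function(means) {
  means <- as.matrix(means)
  if (any(means < 0, na.rm = TRUE)) stop("negative mean density")
  mx <- apply(means, 1L, max, na.rm = TRUE)
  zero <- mx == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero modification row(s) left as zeros")
    mx[zero] <- 1
  }
  sweep(means, 1L, mx, "/")
}

#' Cross-modification signature summary
#'
#' Normalizes each modification's junction profiles by the highest mean value
#' observed for that modification (over all positions and exon sets), then
#' summarizes per exon set the positionwise mean and standard deviation
#' across modifications. Also returns a per-(modification, set) mean-density
#' heat-map table, max-normalized per modification row.
#'
#' @param profiles Nested list: `profiles[[modification]][[set]]` is a
#'   [junction_profile()] result; sets must be consistent across
#'   modifications.
#' @return List: `profile_summary` (data.frame set/window/offset/mean/sd)
#'   and `heatmap` (matrix modifications x sets of normalized mean density).
#' @export
signature_summary <- function(profiles) {
  marks <- names(profiles)
  sets <- names(profiles[[1L]])
  stopifnot(all(vapply(profiles, function(p) identical(names(p), sets),
                       logical(1L))))
  w <- length(profiles[[1L]][[1L]]$acceptor)
  norm_prof <- lapply(marks, function(mk) {
    vals <- lapply(profiles[[mk]], function(p) c(p$acceptor, p$donor))
    top <- max(unlist(vals), na.rm = TRUE)
    if (top == 0) top <- 1
    lapply(vals, function(v) v / top)
  })
  names(norm_prof) <- marks
  summ <- do.call(rbind, lapply(sets, function(st) {
    mat <- do.call(rbind, lapply(marks, function(mk) norm_prof[[mk]][[st]]))
    data.frame(set = st,
               window = rep(c("acceptor", "donor"), each = w),
               offset = rep(seq_len(w), 2L),
               mean = colMeans(mat),
               sd = apply(mat, 2L, stats::sd),
               stringsAsFactors = FALSE)
  }))
  dens <- vapply(marks, function(mk)
    vapply(profiles[[mk]], function(p) p$mean_density, numeric(1L)),
    numeric(length(sets)))
  heat <- normalize_across_sets(t(dens))
  rownames(heat) <- marks; colnames(heat) <- sets
  list(profile_summary = summ, heatmap = heat)
}

#' Drop exons near annotated transcription start sites
#'
#' Retains exons whose boundaries both lie at least `min_distance` bp from
#' every annotated TSS on their contig (exons on contigs without any TSS are
#' retained).
#'
#' @param triplets An `exon_triplets` table.
#' @param tss data.frame with `chrom` and `pos` (0-based TSS positions).
#' @param min_distance Minimum distance in bp (inclusive: exactly
#'   `min_distance` away is retained).
#' @return Filtered `exon_triplets`.
#' @export
tss_distance_filter <- function(triplets, tss, min_distance = 2000L) {
  keep <- vapply(seq_len(nrow(triplets)), function(i) {
    t_pos <- tss$pos[tss$chrom == triplets$chrom[i]]
    if (!length(t_pos)) return(TRUE)
    s <- triplets$start[i]; e <- triplets$end[i]
    inside <- any(t_pos >= s & t_pos < e)
    if (inside) return(FALSE)
    d <- pmin(abs(t_pos - s), abs(t_pos - (e - 1L)))
    min(d) >= min_distance
  }, logical(1L))
  triplets[keep, , drop = FALSE]
}
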