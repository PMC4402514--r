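#' Sign test for exons exceeding both flanks under a 1/3 null
#'
#' Among triplets whose exon/up/down scores are pairwise distinct (after
#' rounding to 10 decimal places to absorb float noise), counts those where
#' the exon exceeds both flanking scores, and computes the upper-tail
#' probability of Binomial(n, 1/3) at the observed count: under exchangeable
#' continuous values, the maximum lands on the exon with probability 1/3.
#'
#' @param exon,up,down Numeric vectors of regional scores (NAs dropped
#'   triplet-wise).
#' @return List of class `sign_test`: `k`, `n`, `p_value`.
#' @export
sign_test <- function(exon, up, down) {
  keep <- !(is.na(exon) | is.na(up) | is.na(down))
  e <- round(exon[keep], 10L); u <- round(up[keep], 10L)
  d <- round(down[keep], 10L)
  distinct <- e != u & e != d & u != d
  n <- sum(distinct)
  if (n == 0L) stop("no informative triplets (all tied or missing)")
  k <- sum(distinct & e > u & e > d)
  p <- stats::pbinom(k - 1L, n, 1 / 3, lower.tail = FALSE)
  structure(list(k = k, n = n, p_value = p), class = "sign_test")
}

#' Permutation-calibrated Pearson correlation
#'
#' Observed Pearson r between `x` and `y`, with an empirical p-value from
#' `n_perm` seeded random permutations of `y`: the count of permutations whose
#' correlation is greater than or equal to the observed one, reported as
#' `(n_geq + 1) / (n_perm + 1)` so the estimate is never exactly zero.
#' Bit-reproducible given `(seed, n_perm)`; the caller's RNG state is
#' restored on exit.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List of class `perm_cor`: `r_observed`, `n_permutations`, `n_geq`,
#'   `p_empirical`, `seed`.
#' @export
permutation_pearson <- function(x, y, n_perm = 10000L, seed = 1L) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  r_obs <- stats::cor(x, y)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(y)
  block <- 2000L  # cap the permutation matrix footprint
  n_geq <- 0L
  done <- 0L
  while (done < n_perm) {
    b <- min(block, n_perm - done)
    idx <- vapply(seq_len(b), function(i) sample.int(n), integer(n))
    r_perm <- as.vector(stats::cor(x, matrix(y[idx], nrow = n)))
    n_geq <- n_geq + sum(r_perm >= r_obs)
    done <- done + b
  }
  structure(list(r_observed = r_obs, n_permutations = n_perm, n_geq = n_geq,
                 p_empirical = (n_geq + 1) / (n_perm + 1), seed = seed),
            class = "perm_cor")
}

#' Wilcoxon rank-sum comparison of two groups
#'
#' Exact enumeration for small tie-free samples (both groups <= 50), normal
#' approximation with tie correction otherwise.
#'
#' @param a,b Numeric vectors.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (a vs b).
#' @return The p-value.
#' @export
rank_sum_compare <- function(a, b, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stop("empty input to rank-sum comparison")
  alt <- sub("two_sided", "two.sided", alternative)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && length(a) <= 50L && length(b) <= 50L
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = alt, exact = exact,
                       correct = FALSE)$p.value)
}

#' Quantile separation between two exon sets
#'
#' Nearest-rank (type-1) quantiles. The first fraction is the share of `low`
#' strictly below the `(1 - cutoff)` quantile of `high`; the second is the
#' share of `high` strictly above the `cutoff` quantile of `low`.
#'
#' @param low,high Non-empty numeric vectors.
#' @param cutoff Quantile cutoff (default 0.9 -> 10th/90th percentiles).
#' @return Named numeric vector `c(low_below, high_above)`.
#' @export
set_separation <- function(low, high, cutoff = 0.9) {
  if (!length(low) || !length(high)) stop("empty input")
  q_high <- stats::quantile(high, 1 - cutoff, type = 1, names = FALSE)
  q_low <- stats::quantile(low, cutoff, type = 1, names = FALSE)
  c(low_below = mean(low < q_high), high_above = mean(high > q_low))
}

#' GC content and base composition deltas between exons and flanks
#'
#' GC fraction = (#G + #C) / region width (ambiguous bases stay in the
#' denominator); base frequencies cover A/C/G/T plus `other`.
#'
#' @param triplets An `exon_triplets` table.
#' @param genome Named `DNAStringSet`.
#' @return data.frame: per-region GC, `d_gc_up` / `d_gc_down` (exon - flank),
#'   and per-region base fractions.
#' @export
composition_deltas <- function(triplets, genome) {
  get_seqs <- function(s, e) {
    lens <- vapply(triplets$chrom, function(ch) length(genome[[ch]]), integer(1L))
    if (any(s < 0L | e > lens)) stop("region beyond contig bounds")
    Biostrings::DNAStringSet(vapply(seq_len(nrow(triplets)), function(i)
      as.character(Biostrings::subseq(genome[[triplets$chrom[i]]],
                                      s[i] + 1L, e[i])), character(1L)))
  }
  comp <- function(ss) {
    w <- Biostrings::width(ss)
    f <- Biostrings::letterFrequency(ss, c("A", "C", "G", "T"))
    gc <- (f[, "C"] + f[, "G"]) / w
    freqs <- f / w
    cbind(gc = gc, freqs, other = 1 - rowSums(freqs))
  }
  ce <- comp(get_seqs(triplets$start, triplets$end))
  cu <- comp(get_seqs(triplets$flank_up_start, triplets$flank_up_end))
  cd <- comp(get_seqs(triplets$flank_down_start, triplets$flank_down_end))
  out <- data.frame(
    exon_key = triplets$exon_key,
    gc_exon = ce[, "gc"], gc_up = cu[, "gc"], gc_down = cd[, "gc"],
    d_gc_up = ce[, "gc"] - cu[, "gc"], d_gc_down = ce[, "gc"] - cd[, "gc"],
    stringsAsFactors = FALSE
  )
  for (b in c("A", "C", "G", "T", "other")) {
    out[[paste0("exon_", b)]] <- ce[, b]
    out[[paste0("up_", b)]] <- cu[, b]
    out[[paste0("down_", b)]] <- cd[, b]
  }
  out
}

#' Expected prevalence of genes carrying a hypomethylated exon
#'
#' Under random placement, a gene with m analyzed exons carries at least one
#' hypomethylated exon with probability 1 - (1 - p)^m, where p is the global
#' hypomethylated fraction. Optionally cross-checks the analytic cohort
#' expectation with a seeded label permutation (shuffling hypo labels across
#' all exons).
#'
#' @param gene_id Character vector, one entry per analyzed exon.
#' @param hypo Logical vector, parallel to `gene_id`.
#' @param n_perm Number of label permutations (0 = analytic only).
#' @param seed Seed for the permutations.
#' @return List: `p_global`, `per_gene` (gene, m, p_any), `expected_genes`,
#'   `observed_genes`, and (if permuted) `perm_mean`, `perm_sd`.
#' @export
gene_level_hypo_expectation <- function(gene_id, hypo, n_perm = 0L, seed = 1L) {
  p <- mean(hypo)
  m <- tapply(hypo, gene_id, length)
  obs <- tapply(hypo, gene_id, any)
  per_gene <- data.frame(gene_id = names(m), m = as.integer(m),
                         p_any = 1 - (1 - p)^as.integer(m),
                         stringsAsFactors = FALSE)
  out <- list(p_global = p, per_gene = per_gene,
              expected_genes = sum(per_gene$p_any),
              observed_genes = sum(obs))
  if (n_perm > 0L) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    counts <- vapply(seq_len(n_perm), function(i) {
      sum(tapply(sample(hypo), gene_id, any))
    }, numeric(1L))
    out$perm_mean <- mean(counts)
    out$perm_sd <- stats::sd(counts)
  }
  out
}

#' Chi-square enrichment of hypomethylated exons across gene thirds
#'
#' Goodness-of-fit of the hypomethylated counts per gene third against the
#' proportions of all analyzed exons, df = 2.
#'
#' @param hypo_counts,all_counts Length-3 integer vectors
#'   (5prime/middle/3prime).
#' @return List: `statistic`, `p_value`, `df`.
#' @export
thirds_enrichment <- function(hypo_counts, all_counts) {
  stopifnot(length(hypo_counts) == 3L, length(all_counts) == 3L)
  if (any(all_counts <= 0)) stop("all_counts must be positive in each bin")
  expected <- sum(hypo_counts) * all_counts / sum(all_counts)
  if (any(expected < 5))
    warning("expected count < 5 in some bin; chi-square asymptotics questionable")
  ct <- suppressWarnings(
    stats::chisq.test(hypo_counts, p = all_counts / sum(all_counts)))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       df = unname(ct$parameter))
}
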