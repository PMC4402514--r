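test_that("sign test counts exon-maximal triplets among pairwise-distinct ones", {
  st <- sign_test(c(0.5, 0.7, 0.4), c(0.2, 0.8, 0.4), c(0.3, 0.1, 0.2))
  expect_equal(st$k, 1L)
  expect_equal(st$n, 2L)          # third triplet tied, excluded
  expect_equal(st$p_value, 5 / 9) # 1 - (2/3)^2
  all_win <- sign_test(rep(1, 20), runif(20, 0, 0.4), runif(20, 0.5, 0.9))
  expect_equal(all_win$p_value, (1 / 3)^20)
  none <- sign_test(rep(0.1, 5), seq(0.2, 0.6, 0.1), seq(0.7, 1.1, 0.1))
  expect_equal(none$p_value, 1.0)
  expect_error(sign_test(c(1, 2), c(1, 2), c(1, 2)), "no informative")
})

test_that("permutation Pearson p is seeded, reproducible, and affine-invariant", {
  x <- as.numeric(1:50)
  r1 <- permutation_pearson(x, x, 1000L, seed = 5L)
  expect_equal(r1$r_observed, 1.0)
  expect_lte(r1$p_empirical, 2 / 1001)
  r2 <- permutation_pearson(x, x, 1000L, seed = 5L)
  expect_identical(r1, r2)  # bit-for-bit
  # translation/scaling of either input leaves the permutation count unchanged
  r3 <- permutation_pearson(3 * x + 7, 0.5 * x + 2, 1000L, seed = 5L)
  expect_equal(r3$n_geq, r1$n_geq)
  rev_r <- permutation_pearson(x, rev(x), 500L, seed = 5L)
  expect_equal(rev_r$r_observed, -1.0)
  expect_gt(rev_r$p_empirical, 0.99)
  expect_error(permutation_pearson(rep(1, 10), rnorm(10)), "variance")
  # caller RNG state is untouched
  xx <- rnorm(20); yy <- rnorm(20)
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(permutation_pearson(xx, yy, 50L, 3L))
  expect_identical(rnorm(1), before)
})

test_that("rank-sum comparison matches exact enumeration and sidedness", {
  expect_equal(rank_sum_compare(c(1, 2, 3), c(4, 5, 6)), 2 / 20) # C(6,3) oracle
  expect_equal(rank_sum_compare(c(1, 2, 3), c(1, 2, 3)), 1.0)
  a <- rnorm(100); b <- rnorm(100) + 5
  expect_lt(rank_sum_compare(a, b), 1e-10)
  expect_lt(rank_sum_compare(a, b, "less"), 1e-10)
  expect_gt(rank_sum_compare(a, b, "greater"), 0.99)
  expect_error(rank_sum_compare(numeric(0), 1), "empty")
})

test_that("set separation uses nearest-rank quantiles with strict counting", {
  low <- c(0.1, 0.2, 0.3, 0.4, 0.5); high <- c(0.3, 0.6, 0.7, 0.8, 0.9)
  got <- set_separation(low, high)
  expect_equal(unname(got["low_below"]), 2 / 5)   # 10th pct of high = 0.3
  expect_equal(unname(got["high_above"]), 4 / 5)  # 90th pct of low = 0.5
  # complete separation
  expect_equal(unname(set_separation(1:5 / 10, 6:10 / 10)), c(1, 1))
  # self-separation is bounded near 1 - cutoff
  set.seed(3)
  v <- rnorm(200)
  self <- set_separation(v, v)
  expect_true(all(self <= 0.1 + 1 / 200 + 1e-12))
  # invariance under strictly monotone transforms
  tr <- function(z) exp(z / 2)
  expect_equal(set_separation(tr(low), tr(high)), got)
})

test_that("set separation matches a brute-force oracle on random pairs", {
  set.seed(17)
  oracle <- function(low, high, cutoff = 0.9) {
    nr <- function(v, q) sort(v)[max(1L, ceiling(q * length(v)))]
    c(low_below = mean(low < nr(high, 1 - cutoff)),
      high_above = mean(high > nr(low, cutoff)))
  }
  for (i in 1:200) {
    lo <- rnorm(sample(3:30, 1)); hi <- rnorm(sample(3:30, 1), mean = 1)
    expect_equal(set_separation(lo, hi), oracle(lo, hi))
  }
})

test_that("GC deltas come out of the sequence with N in the denominator", {
  # exon GCGC at [200, 204), flanks all AT
  seqs <- paste0(strrep("AT", 100), "GCGC", strrep("AT", 100))
  genome <- Biostrings::DNAStringSet(seqs); names(genome) <- "chr1"
  tri <- tri_df(200L, 204L)
  cd <- composition_deltas(tri, genome)
  expect_equal(cd$gc_exon, 1.0)
  expect_equal(c(cd$d_gc_up, cd$d_gc_down), c(1, 1))
  # ACGT repeats: gc 0.5 everywhere, deltas 0
  g2 <- Biostrings::DNAStringSet(strrep("ACGT", 200)); names(g2) <- "chr1"
  cd2 <- composition_deltas(tri, g2)
  expect_equal(cd2$gc_exon, 0.5)
  expect_equal(c(cd2$d_gc_up, cd2$d_gc_down), c(0, 0))
  # ambiguous bases stay in the denominator
  g3 <- Biostrings::DNAStringSet(paste0(strrep("A", 200), "ACGN",
                                        strrep("A", 200)))
  names(g3) <- "chr1"
  tri3 <- tri_df(200L, 204L)
  cd3 <- composition_deltas(tri3, g3)
  expect_equal(cd3$gc_exon, 0.5)
  expect_equal(cd3$exon_other, 0.25)
  expect_error(composition_deltas(tri_df(10L, 100L), g3), "contig")
})

test_that("gene-level hypo expectation is analytic with a permutation cross-check", {
  g <- gene_level_hypo_expectation(rep("g1", 3), c(TRUE, FALSE, FALSE))
  # p = 1/3 here; also check the closed form at p = 0.1, m = 3
  expect_equal(1 - (1 - 0.1)^3, 0.271)
  expect_equal(g$per_gene$p_any, 1 - (2 / 3)^3)
  g0 <- gene_level_hypo_expectation(rep(c("a", "b"), each = 4), rep(FALSE, 8))
  expect_equal(g0$expected_genes, 0)
  # permutation mean tracks the analytic expectation on a synthetic cohort
  set.seed(12)
  gene_id <- rep(sprintf("g%03d", 1:100), times = sample(3:8, 100, TRUE))
  hypo <- runif(length(gene_id)) < 0.15
  gg <- gene_level_hypo_expectation(gene_id, hypo, n_perm = 200L, seed = 4L)
  se <- gg$perm_sd / sqrt(200)
  # fixed-total permutation vs binomial analytic: allow 3 SE plus the small
  # systematic gap between the two nulls
  expect_lt(abs(gg$perm_mean - gg$expected_genes), 3 * se + 1)
})

test_that("thirds enrichment is a df=2 goodness-of-fit against the exon background", {
  prop <- thirds_enrichment(c(20L, 20L, 20L), c(100L, 100L, 100L))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)
  hand <- thirds_enrichment(c(30L, 10L, 10L), c(100L, 100L, 100L))
  expect_equal(hand$statistic, 16.0)  # sum (O-E)^2/E with E = 50/3
  expect_equal(hand$df, 2)
  conc <- thirds_enrichment(c(60L, 0L, 0L), c(100L, 100L, 100L))
  expect_lt(conc$p_value, 0.001)
  expect_warning(thirds_enrichment(c(3L, 1L, 1L), c(50L, 50L, 50L)),
                 "expected count")
  expect_error(thirds_enrichment(c(1L, 1L, 1L), c(5L, 0L, 5L)), "positive")
})
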