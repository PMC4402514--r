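test_that("bedGraph and wiggle tracks expand to per-base values with masks", {
  bg <- tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t10\t2.5", "chr1\t20\t25\t1.0"), bg)
  tr <- load_signal(bg, "bedGraph")
  expect_equal(track_values(tr, "chr1", 0L, 10L), rep(2.5, 10))
  expect_true(all(is.na(track_values(tr, "chr1", 10L, 20L))))  # gap masked
  expect_equal(track_values(tr, "chr1", 20L, 25L), rep(1, 5))

  wig <- tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=chr1 start=1 step=1 span=1",
               as.character(c(2.5, 2.5, 3, 4))), wig)
  tw <- load_signal(wig, "wiggle")
  expect_equal(track_values(tw, "chr1", 0L, 4L), c(2.5, 2.5, 3, 4))

  bad <- tempfile(); writeLines(c("chr1\t0\t10\t1", "chr1\t5\t15\t2"), bad)
  expect_error(load_signal(bad, "bedGraph"), "overlapping")
  neg <- tempfile(); writeLines("chr1\t0\t10\t-1", neg)
  expect_error(load_signal(neg, "bedGraph"), "negative")
})

test_that("H3 occupancy dedups by (position, strand) and smooths over 18 bp", {
  L <- c(chr1 = 1000L)
  reads <- data.frame(chrom = "chr1", pos = c(100L, 100L, 100L, 100L),
                      strand = c("+", "+", "+", "-"))
  tr <- h3_occupancy(reads, 18L, L)
  # three + duplicates collapse to one; the - read at the same position stays
  expect_equal(sum(tr$values$chr1), 2)
  # a unit spike spreads 1/18 over exactly positions p-8 .. p+9
  spike <- h3_occupancy(data.frame(chrom = "chr1", pos = 500L, strand = "+"),
                        18L, L)
  v <- spike$values$chr1
  covered <- which(v > 0) - 1L   # back to 0-based
  expect_equal(covered, 492:509)
  expect_equal(unique(v[covered + 1L]), 1 / 18)
  # constant raw coverage stays constant in the interior
  const <- h3_occupancy(data.frame(chrom = "chr1", pos = 0:999,
                                   strand = "+"), 18L, L)
  expect_equal(unique(const$values$chr1[10:990]), 1)
  # smoothing conserves mass away from edges
  set.seed(5)
  rr <- data.frame(chrom = "chr1", pos = sample(100:900, 300, TRUE),
                   strand = sample(c("+", "-"), 300, TRUE))
  sm <- h3_occupancy(rr, 18L, L)
  dd <- rr[!duplicated(paste(rr$pos, rr$strand)), ]
  expect_equal(sum(sm$values$chr1), nrow(dd))
})

test_that("junction profiles reproduce a distance-function track exactly", {
  # track value = genomic position, so profiles reveal the exact bookkeeping
  L <- 5000L
  tr <- toy_track(as.numeric(0:(L - 1)))
  plus <- tri_df(1000L, 1400L, "+")
  jp <- junction_profile(plus, tr)
  expect_equal(jp$acceptor, as.numeric(800:1099))   # 200 intronic + 100 exonic
  expect_equal(jp$donor, as.numeric(1300:1599))     # 100 exonic + 200 intronic
  minus <- tri_df(1000L, 1400L, "-")
  jm <- junction_profile(minus, tr)
  expect_equal(jm$acceptor, as.numeric(1599:1300))  # upstream intron is right
  expect_equal(jm$donor, as.numeric(1099:800))
  expect_equal(jp$n_exons_used, 1L)
})

test_that("exons with masked or short windows are dropped per window", {
  v <- rep(2, 5000); v[900] <- NA  # 0-based 899: inside the acceptor window
  tr <- toy_track(v)
  tri <- tri_df(c(1000L, 3000L), c(1400L, 3400L))
  jp <- junction_profile(tri, tr)
  expect_equal(jp$n_acceptor, 1L)  # first exon dropped from acceptor only
  expect_equal(jp$n_donor, 2L)
  expect_equal(unique(jp$acceptor), 2)
  # exon shorter than the exonic sub-window is skipped entirely
  short <- tri_df(c(1000L, 3000L), c(1099L, 3400L))
  expect_equal(junction_profile(short, tr)$n_exons_used, 1L)
  # every window outside the contig -> nothing usable
  expect_error(junction_profile(tri_df(10L, 400L), toy_track(rep(2, 50))),
               "complete data")
})

test_that("profiles are invariant under genome mirroring", {
  set.seed(21)
  L <- 6000L
  v <- rpois(L, 3) + runif(L)
  exons <- tri_df(c(1000L, 3500L), c(1350L, 3800L), c("+", "-"))
  fwd <- lapply(seq_len(nrow(exons)), function(i)
    junction_profile(exons[i, ], toy_track(v)))
  # mirror: position p -> L-1-p, strands flip
  mv <- rev(v)
  ms <- L - exons$end; me <- L - exons$start
  mirrored <- tri_df(ms, me, ifelse(exons$strand == "+", "-", "+"))
  bwd <- lapply(seq_len(nrow(mirrored)), function(i)
    junction_profile(mirrored[i, ], toy_track(mv)))
  for (i in 1:2) {
    expect_equal(bwd[[i]]$acceptor, fwd[[i]]$acceptor)
    expect_equal(bwd[[i]]$donor, fwd[[i]]$donor)
  }
})

test_that("max normalization is per-row, idempotent, and scale invariant", {
  m <- rbind(a = c(4, 2), b = c(3, 3), c = c(0, 0))
  expect_warning(nm <- normalize_across_sets(m), "all-zero")
  expect_equal(nm["a", ], c(1, 0.5))
  expect_equal(nm["b", ], c(1, 1))
  expect_equal(nm["c", ], c(0, 0))
  nm2 <- suppressWarnings(normalize_across_sets(nm))
  expect_equal(nm2, nm)                       # idempotent
  expect_equal(suppressWarnings(normalize_across_sets(m * 17)), nm)
  expect_error(normalize_across_sets(rbind(c(-1, 2))), "negative")
})

test_that("signature summary averages normalized profiles across marks", {
  tr <- toy_track(rep(2, 3000))
  tri <- tri_df(1000L, 1400L)
  jp <- junction_profile(tri, tr)
  profiles <- list(m1 = list(setA = jp, setB = jp),
                   m2 = list(setA = jp, setB = jp))
  ss <- signature_summary(profiles)
  expect_true(all(ss$profile_summary$sd == 0))   # identical marks
  expect_true(all(ss$profile_summary$mean == 1)) # constant track -> max-normalized 1
  expect_equal(dim(ss$heatmap), c(2L, 2L))
  one <- signature_summary(list(only = list(s = jp)))
  expect_equal(one$profile_summary$mean,
               c(jp$acceptor, jp$donor) / max(jp$acceptor))
})

test_that("TSS distance control keeps exons at least 2 kb from any start site", {
  tri <- tri_df(c(10000L, 30000L, 50000L), c(10300L, 30300L, 50300L))
  # 1999 bp from exon 1's last base -> removed; exactly 2000 bp -> retained
  tss <- data.frame(chrom = "chr1", pos = c(10299L + 1999L, 30299L + 2000L))
  kept <- tss_distance_filter(tri, tss)
  expect_setequal(kept$exon_key, tri$exon_key[2:3])
  none <- tss_distance_filter(tri, data.frame(chrom = "chr9", pos = 1L))
  expect_equal(nrow(none), 3L)
  inside <- tss_distance_filter(tri, data.frame(chrom = "chr1", pos = 30100L))
  expect_false(tri$exon_key[2] %in% inside$exon_key)
})
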