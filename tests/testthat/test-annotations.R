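test_that("GTF and BED12 loaders normalize to 0-based half-open coordinates", {
  gtf <- write_toy_gtf(data.frame(
    chrom = "chr1", start = c(100L, 500L), end = c(200L, 650L), strand = "+",
    gene_id = "gA", transcript_id = "tA"))
  tx <- load_transcripts(gtf, "GTF")
  expect_equal(tx$start, c(100L, 500L))  # GTF col 4 was 101
  expect_equal(tx$end, c(200L, 650L))
  expect_equal(tx$exon_rank, c(1, 2))

  bed <- tempfile(fileext = ".bed")
  # one transcript, chromStart 100, 3 blocks of 50 at offsets 0/200/400
  writeLines(paste(c("chr1", 100, 600, "tB", 0, "-", 100, 600, "0", 3,
                     "50,50,50", "0,200,400"), collapse = "\t"), bed)
  txb <- load_transcripts(bed, "BED12")
  expect_equal(nrow(txb), 3L)
  expect_equal(txb$start, c(100L, 300L, 500L))
  expect_equal(txb$end, c(150L, 350L, 550L))
  expect_equal(unique(txb$strand), "-")

  bad <- write_toy_gtf(data.frame(
    chrom = "chr1", start = c(100L, 150L), end = c(200L, 260L), strand = "+",
    gene_id = "gA", transcript_id = "tA"))
  expect_error(load_transcripts(bad, "GTF"), "overlapping")
})

test_that("internal-exon selection recovers the programmed internal set exactly", {
  # gene gA (+): 5 exons, introns 601 -> internal candidates e2,e3,e4.
  # transcript tB reuses e4 as its LAST exon -> e4 must drop out.
  # gene gC: internal exon with a 500-nt upstream intron -> excluded.
  gA <- data.frame(chrom = "chr1",
                   start = c(1000L, 1701L, 2402L, 3103L, 3804L),
                   end   = c(1100L, 1801L, 2502L, 3203L, 3904L),
                   strand = "+", gene_id = "gA",
                   transcript_id = "tA")
  gB <- data.frame(chrom = "chr1", start = c(200L, 3103L),
                   end = c(300L, 3203L), strand = "+", gene_id = "gA",
                   transcript_id = "tB")
  gC <- data.frame(chrom = "chr2",
                   start = c(1000L, 1601L, 2302L),
                   end   = c(1100L, 1701L, 2402L),
                   strand = "+", gene_id = "gC", transcript_id = "tC")
  tx <- toy_tx(rbind(gA, gB, gC))
  sel <- suppressMessages(select_internal_exons(tx, min_intron = 600L))
  expect_setequal(sel$exon_key, c("chr1:1701-1801:+", "chr1:2402-2502:+"))
  # flanks abut the splice sites
  expect_equal(sel$flank_up_end, sel$start)
  expect_equal(sel$flank_down_start, sel$end)
  # order independence / idempotence
  shuffled <- toy_tx(rbind(gC, gB, gA)[sample(nrow(gA) + nrow(gB) + nrow(gC)), ])
  sel2 <- suppressMessages(select_internal_exons(shuffled, min_intron = 600L))
  expect_identical(sel, sel2)
})

test_that("TSS/TES overlap filter removes exons whose analyzed region hits a gene end", {
  gA <- data.frame(chrom = "chr1",
                   start = c(1000L, 1701L, 2402L),
                   end   = c(1100L, 1801L, 2502L),
                   strand = "+", gene_id = "gA", transcript_id = "tA")
  # single-exon transcript whose TSS (5000) is far away: no effect
  far <- data.frame(chrom = "chr1", start = 5000L, end = 5100L,
                    strand = "+", gene_id = "gX", transcript_id = "tX")
  tx <- toy_tx(rbind(gA, far))
  sel <- suppressMessages(select_internal_exons(tx, min_intron = 600L))
  expect_equal(sel$exon_key, "chr1:1701-1801:+")
  # a transcript starting inside the upstream flank region kills the exon
  near <- data.frame(chrom = "chr1", start = 1550L, end = 5100L,
                     strand = "+", gene_id = "gX", transcript_id = "tX")
  tx2 <- toy_tx(rbind(gA, near))
  sel2 <- suppressMessages(select_internal_exons(tx2, min_intron = 600L))
  expect_equal(nrow(sel2), 0L)
  expect_warning(suppressMessages(select_internal_exons(tx[0, ])), "empty")
})

test_that("flank geometry is mirrored in transcription orientation on a cohort", {
  sim <- local_sim()
  tx <- load_transcripts(sim$paths$gtf, "GTF")
  sel <- suppressMessages(select_internal_exons(tx))
  sel <- define_mid_intron_regions(sel)
  plus <- sel$strand == "+"
  expect_true(all(sel$flank_up_end[plus] == sel$start[plus]))
  expect_true(all(sel$flank_down_start[plus] == sel$end[plus]))
  expect_true(all(sel$flank_up_start[!plus] == sel$end[!plus]))
  expect_true(all(sel$flank_down_end[!plus] == sel$start[!plus]))
  expect_setequal(sel$exon_key, sim$truth$exon_key)
  # mid regions sit inside the introns, clear of the flanks
  up_gap <- ifelse(plus, sel$flank_up_start - sel$mid_up_end,
                   sel$mid_up_start - sel$flank_up_end)
  expect_true(all(up_gap > 0))
})

test_that("EST classification follows the inclusion-rate brackets", {
  expect_equal(classify_by_est(c(1, 0.5, 0.97, 0.05, 0.95, 0.02, NA)),
               c("constitutive", "alternative", "other", "alternative",
                 "alternative", "other", "other"))
  expect_error(classify_by_est(1.2), "outside")
  tri <- tri_df(1000L, 1300L)
  est <- data.frame(chrom = "chr1", start = 1000L, end = 1300L, strand = "+",
                    rate = 1)
  expect_equal(attach_est(tri, est)$est_class, "constitutive")
})

test_that("TATA promoter scan agrees with a regex oracle on random sequence", {
  set.seed(42)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  genome <- Biostrings::DNAStringSet(s); names(genome) <- "chr1"
  oracle <- function(str) length(gregexpr("TATA[AT]A[AT][AG]", str)[[1]]) > 0 &&
    gregexpr("TATA[AT]A[AT][AG]", str)[[1]][1] != -1
  for (tss in c(1000L, 2500L, 6000L, 9990L)) {
    up <- substring(s, max(tss - 1000, 0) + 1, tss)
    got <- if (tss + 1000 <= 10000)
      annotate_tata_promoter(tss, "+", "chr1", genome) else
      suppressWarnings(annotate_tata_promoter(tss, "+", "chr1", genome))
    expect_identical(got, oracle(up), info = paste("tss", tss))
  }
  # minus strand: scan is on the reverse complement downstream of the TSS
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  tss <- 4000L
  up_minus <- rc(substring(s, tss + 2, tss + 1001))
  expect_identical(annotate_tata_promoter(tss, "-", "chr1", genome),
                   oracle(up_minus))
  # degenerate cases
  g2 <- Biostrings::DNAStringSet(c(chrN = paste(rep("N", 3000), collapse = "")))
  expect_false(annotate_tata_promoter(2000L, "+", "chrN", g2))
  g3 <- Biostrings::DNAStringSet(c(chr = paste0(strrep("C", 1500), "TATACAAG",
                                                strrep("C", 500))))
  expect_false(annotate_tata_promoter(1900L, "+", "chr", g3))
  g3b <- Biostrings::DNAStringSet(c(chr = paste0(strrep("C", 1500), "TATAAAAG",
                                                 strrep("C", 500))))
  expect_true(annotate_tata_promoter(1900L, "+", "chr", g3b))
})

test_that("gene thirds assign midpoints by half-open segments in transcription order", {
  # enumeration oracle over all width-2 exons in gene [0, 300)
  starts <- 0:298
  got <- assign_gene_third(starts, starts + 2L, 0L, 300L, "+")
  mids <- starts + 1
  want <- c("5prime", "middle", "3prime")[pmin(floor(mids / 100), 2) + 1]
  expect_equal(got, want)
  expect_equal(assign_gene_third(149L, 151L, 0L, 300L, "+"), "middle")
  expect_equal(assign_gene_third(249L, 251L, 0L, 300L, "-"), "5prime")
  expect_equal(assign_gene_third(99L, 101L, 0L, 300L, "+"), "middle")  # boundary
  expect_error(assign_gene_third(400L, 420L, 0L, 300L, "+"), "outside")
})

test_that("mid-intron regions take the centered window and vanish on short introns", {
  # + strand exon at 1000 with a 1000-nt upstream intron [0, 1000)
  tri <- tri_df(1000L, 1300L); tri$intron_up <- 1000L; tri$intron_down <- 1000L
  out <- define_mid_intron_regions(tri)
  expect_equal(c(out$mid_up_start, out$mid_up_end), c(400L, 600L))
  # odd remainder floors the left offset: intron [0, 1001) for exon at 1001
  tri2 <- tri_df(1001L, 1300L); tri2$intron_up <- 1001L; tri2$intron_down <- 1001L
  out2 <- define_mid_intron_regions(tri2)
  expect_equal(c(out2$mid_up_start, out2$mid_up_end), c(400L, 600L))
  # boundary of existence: > width + 400 required
  tri3 <- tri_df(1000L, 1300L); tri3$intron_up <- 600L; tri3$intron_down <- 601L
  out3 <- define_mid_intron_regions(tri3)
  expect_true(is.na(out3$mid_up_start))
  expect_false(is.na(out3$mid_down_start))
})
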