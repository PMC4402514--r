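---
title: "Regional DNA methylation at internal exons: model, pipeline and synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional DNA methylation at internal exons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonmeth)
```

## The scientific problem

Gene-body DNA methylation in vertebrates is not uniform: exons are usually
more methylated than their intronic surroundings, and intragenic methylation
rises with transcription. Within that majority behaviour hides a minority of
*hypomethylated* internal exons — regional methylation below 0.5 and below
both flanking introns — that carry a very different chromatin state at high
expression: dense histone marking, DNase accessibility and predicted-enhancer
overlap. `exonmeth` provides the pieces needed to quantify both behaviours
from whole-genome bisulfite calls, transcript-level FPKM, signal tracks and
interval sets, and a generator of fully ground-truthed synthetic cohorts to
validate every step.

## The analyzed exon universe

Internal exons are exons that are neither first nor last **in any
transcript** in which they appear (coordinate-identical exons are
deduplicated across transcripts). Retained exons must be flanked by introns
longer than 600 nt — which guarantees the 200-nt flanking windows are fully
intronic and leaves room for mid-intron controls — and the analyzed region
(upstream flank + exon + downstream flank) must not contain any annotated
transcription start or end. "Upstream" and "downstream" are defined in
transcription orientation throughout: for a minus-strand exon the
genomically-right intron is upstream. This orientation convention is the
biologically coherent reading of splice-site vocabulary; the alternative
(genomic left/right) would average acceptor and donor behaviour and blur the
junction profiles.

Two deliberate interpretation choices, both configurable:

* The TSS/TES filter is applied to the analyzed region (flanks + exon), not
  to the full introns; `filter_scope = "introns"` gives the stricter variant.
  Applying it to the exon as well as the flanks is a safety extension — a
  start site inside the exon itself would contaminate the comparison.
* Mid-intron control regions are the central 200 nt of each flanking intron
  (left-floored for odd remainders), defined only when the intron exceeds
  `width + 400` nt so a mid region can never touch a flank. The width matches
  the flanks so scores are directly comparable.

Coordinates are 0-based half-open everywhere inside the package; GTF input is
converted at the boundary. Gene thirds (5′ / middle / 3′) split the gene span
into three equal-length half-open segments and assign each exon by midpoint,
with boundary midpoints going to the genomically-downstream segment.

## Methylation scores and classification

A CpG site qualifies with read coverage strictly greater than 4 (at least 5
reads); its rate is methylated-supporting reads over total. A region's score
is the **unweighted mean** of qualifying site rates — weighting by coverage
would let a single deep site dominate a region, and the regional-average
formulation treats sites as exchangeable draws of the regional state. A
region with no qualifying site is *missing*, not zero.

Comparative analyses apply the coupled-region correction: a triplet
contributes deltas (exon − upstream flank, exon − downstream flank) only when
all three regions are measurable. Because CpG density differs systematically
between exons and introns, dropping incomplete triplets prevents
composition-driven selection bias from masquerading as a methylation
difference.

Exons with score < 0.5 are hypomethylated, ≥ 0.5 methylated (the boundary is
assigned to the methylated side; scores land exactly on 0.5 only with tiny
site counts), unscored when missing.

## Expression, inclusion and tiers

Exon expression is the FPKM sum of the transcripts containing a
coordinate-identical exon; gene expression sums all same-strand transcripts
overlapping the containing locus; inclusion is their ratio, capped at 1.
Expression tiers take the bottom and top `floor(0.2 · n)` exons among those
with FPKM > 0, with ties broken by exon key so the partition is deterministic
under input reordering. Correlation analyses use natural log of FPKM
restricted to positive values; the log base only rescales r, never the
permutation p.

## Differential statistics

* **Sign test.** Under exchangeable continuous triplet values, the exon is
  the maximum with probability 1/3. Triplets are "informative" when the three
  values are pairwise distinct after rounding to 10 decimals (absorbing float
  noise); p is the exact Binomial(n, 1/3) upper tail.
* **Permutation Pearson.** p = (n_geq + 1)/(n_perm + 1), never exactly zero;
  the raw count is retained so "< 1/n_perm"-style bounds can be stated.
  Defaults: 10,000 permutations for methylation~expression, 1,000 for the
  delta–delta correlation. Given `(seed, n_perm)` the result is
  bit-reproducible, and the caller's RNG state is restored.
* **Rank-sum comparisons** default to two-sided; exact enumeration for
  tie-free samples up to 50 per group, normal approximation with tie
  correction beyond.
* **Quintile separation** uses nearest-rank (type-1) quantiles and strict
  inequalities: the share of the low set strictly below the high set's 10th
  percentile, and vice versa at the 90th.
* **GC composition** counts G+C over the full region width, so ambiguous
  bases dilute rather than inflate GC.
* **Gene-level expectation.** With global hypomethylated fraction p, a gene
  with m analyzed exons carries ≥ 1 hypomethylated exon with probability
  1 − (1 − p)^m; a label-permutation null (which fixes the total count) is
  provided as a cross-check and agrees closely for cohorts of this size.
* **Thirds enrichment** is a df = 2 chi-square goodness-of-fit of the
  hypomethylated counts against the all-exon proportions.

## Chromatin profiles

Junction profiles cover 200 intronic + 100 exonic nt at the acceptor and
100 exonic + 200 intronic nt at the donor, positionally reversed for
minus-strand exons. Exons shorter than 100 nt are excluded (their windows
would cross the opposite junction); an exon with any masked base in a window
is dropped from that window only. Loaded tracks distinguish "no data" (masked)
from zero.

H3 occupancy deduplicates reads by (position, strand) — alignment start on
+, stop on − — and smooths per-base counts with an 18-bp running mean. The
even window is split 9 left / 8 right of the focal base; the choice is
arbitrary but fixed, and mass is conserved away from contig edges.

Across modifications, mean densities are max-normalized per modification
(each row divided by its maximum over exon sets, so every row peaks at
exactly 1), and the cross-modification signature reports the positionwise
mean ± one standard deviation **across modifications** (not across exons).
Mean density per (modification, set) averages the acceptor and donor windows.

## Overlap analyses

Overlap is exon-body only (flanks excluded), half-open, ≥ 1 bp: abutment is
not overlap. Per-exon hotspot scores take the maximum over overlapping
regions (`mean` available); enhancer calls expand to midpoint ± 500 bp,
unmerged, clamped at contig start.

## The synthetic cohort generator

`sim_config()` defaults define the package's standard study conditions:

| parameter | default | meaning |
|---|---|---|
| genes × exons | 120 × 7 | 5 internal exons per gene, 600 total |
| exon / intron / spacer | 300 / 800 / 3000 nt | introns clear the 600-nt filter and admit mid regions |
| CpG rate | 0.12 per bp | 36 CpGs per exon, 24 per flank, grid-placed |
| depth | Poisson(30) | methylated reads Binomial(depth, μ) |
| expression | log-normal(1, 1) | one transcript per gene; constitutive exons inherit gene FPKM |
| tier baselines μ | 0.60 / 0.72 / 0.85 | flank methylation by expression tier |
| hill delta | +0.1 | exon μ above its flanks |
| dip fraction | 1/6 | dip exon μ ~ Uniform(0.15, 0.30) |
| missing fraction | 0.02 | upstream flank emitted at coverage 3 |
| hotspot / enhancer coverage | 0.40 / 0.30 | of dip exons in the high tier |

CpG sites sit on a fixed-phase grid (count = round(rate × width)) rather
than per-bp Bernoulli draws: this guarantees every scored region actually
contains CpGs at the configured density, so coverage-driven missingness is
controlled by `missing_fraction` alone rather than by placement noise. Read
depth and methylated-read sampling remain stochastic (Poisson × Binomial),
which is the simplest generative model consistent with bisulfite count data.
The genome is sampled at GC 0.55 in exons vs 0.40 in introns, with CG
dinucleotides forced at call positions. Histone tracks are triangular bumps
spanning exon ± 200 bp whose amplitude depends on (tier, class) — by default
3:1 in favour of hypomethylated high-expression exons for every mark except
the last, "H3K36me3-like" mark, which prefers methylated high-expression
exons — plus per-base Poisson noise. H3 read starts are uniform with a 10%
duplicate injection.

Two scenarios recur in the tests and the acceptance script:

* **Default cohort** (500 hill / 100 dip, constant delta +0.1): used for
  recovery checks — classification accuracy, delta bias, hotspot coverage.
* **Structural cohort**: tier-dependent hill deltas (0.15 / 0.10 / 0.05 for
  low / mid / high) reproducing the published contrast that exon–flank
  elevation is larger at low expression, and a dip prevalence of 6.5%
  matching the observed prevalence of hypomethylated exons among scored
  constitutive exons. The prevalence matters: dips are extreme values, and
  at a 1/6 fraction their random placement across tiers adds enough variance
  to obscure the methylation–expression correlation in a 600-exon cohort.

What the generator does *not* emulate: CpG islands, distance-decay
correlation of methylation, non-CpG contexts, isoform mixtures (inclusion is
exercised through the EST-rate input instead), mappability or coverage
artifacts, and realistic chromatin-state segmentation. Passing tests
therefore demonstrate correctness of the *computations* under the stated
generative model, not robustness to every failure mode of real bisulfite
data.

## Numerical and degenerate-input choices

* Empirical permutation p uses the (n+1)/(N+1) estimator; raw counts are kept.
* Sign-test tie handling rounds to 10 decimals before the distinctness test.
* All-zero modification rows stay zero under max normalization, with a
  warning rather than NaN.
* Regions beyond contig bounds are errors in sequence space but masked in
  signal space (tracks legitimately cover subsets of the genome).
* Zero-variance inputs to correlation, empty exon sets, and coverage tables
  with meth > total are hard errors, not silent NA propagation.
* Seeds: every stochastic operation takes an explicit seed, records it in its
  output, and restores the caller's RNG state.

## Problem sizes used in validation

The shipped validation uses cohorts of 120 genes / 600 internal exons (the
default conditions above), 100,000-triplet null calibrations, 1,000-cohort
type-I-error sweeps, 500-replicate uniformity checks of the permutation p,
and 250-instance brute-force equivalence sweeps per oracle. These sizes give
standard errors comfortably inside the asserted tolerances (e.g. the
exon-maximal fraction is estimated to ±0.0045 at 3·SE) while keeping the
whole suite fast on a single CPU.

## Known limitations

* Exon–transcript membership is exact-coordinate, mirroring RefSeq-style
  annotations; containment-based matching would need a different notion of
  exon identity.
* The wiggle reader supports fixedStep/variableStep via `rtracklayer`; BAM
  input, bigWig and peak calling are out of scope — the pipeline consumes
  already-processed tracks.
* No multiple-testing layer: the analysis reports raw p-values per
  comparison, as the statistics here are few and pre-registered by design.
* Gene expression for an exon sums same-strand transcripts overlapping its
  locus; antisense contributions are deliberately excluded.
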