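# exonmeth

Differential DNA methylation at internal exons versus their flanking introns.

In vertebrate gene bodies, exons are on average more methylated than the
introns around them, and intragenic methylation tracks transcription. But the
exome is not homogeneous: alongside the majority "hill" exons (more methylated
than both 200-nt flanking intron windows) sits a distinct minority of
hypomethylated "dip" exons whose regional methylation falls below 0.5 and
below their surroundings, and which — at high expression — carry open
chromatin, dense histone marking and predicted-enhancer overlap. `exonmeth`
implements the complete analysis needed to find and characterize these
classes from standard inputs (gene models, a per-CpG bisulfite call table,
transcript FPKM, signal tracks, interval BEDs), plus a ground-truthed
synthetic-cohort generator so the whole pipeline is testable without any
external downloads.

## The statistics at the core

* **Regional methylation score.** Each CpG site with read coverage > 4 gets a
  rate m/t; a region's score is the unweighted mean over qualifying sites,
  with an explicit missing state when none qualify. Exon–flank comparisons
  use a *coupled-region correction*: a triplet (exon, upstream 200 nt,
  downstream 200 nt) enters comparative analyses only when all three regions
  are measurable, avoiding CpG-selection bias between exons and introns.
* **Sign test with a 1/3 null.** Among triplets whose three scores are
  pairwise distinct, the exon exceeds both flanks with probability 1/3 under
  exchangeability; the p-value is the upper Binomial(n, 1/3) tail at the
  observed count k.
* **Permutation-calibrated Pearson correlations.** Observed r against the
  null distribution from seeded permutations of one variable (10,000 for
  methylation~expression, 1,000 for the upstream-delta~downstream-delta
  correlation), reported as (n_geq + 1) / (n_perm + 1).
* **Junction metaprofiles.** Per-base signal averaged over exons in
  transcription orientation across the acceptor (200 intronic + 100 exonic
  nt) and donor (100 exonic + 200 intronic nt) windows, complete-data only;
  per-modification max normalization across exon sets; H3 occupancy from
  read starts with positional dedup and 18-bp smoothing.
* **Overlap analyses.** Half-open 1-bp-minimum intersection of exon bodies
  with DNase-I hotspots and midpoint±500 bp enhancer windows; per-exon
  hotspot score = max over overlapping regions.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
cohorts; each is a thin driver over the package functions.

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_exons_methylation.R
```

prints (abridged):

```
default cohort: 600 internal exons (500 hill, 100 dip), genome 1,189,000 bp
scored 600 exons: 500 methylated, 100 hypomethylated, 0 unscored
12 triplets excluded by the coupled-region correction
exon > both flanks in 491 of 588 informative triplets (p = 5.01e-139, 1/3 null)
```

i.e. the classifier recovers exactly the programmed 500/100 hill/dip split,
the coupled-region correction removes the 2% of exons whose upstream flank
was emitted below the coverage threshold, and the sign test rejects the 1/3
null overwhelmingly because 5/6 of exons were programmed as hills.
Continuing,

```sh
Rscript analysis/03_expression_stats.R
Rscript analysis/04_chromatin.R
Rscript analysis/05_overlap.R
```

```
methylation~log(FPKM): r = 0.27, permutation p = 0.0001
deltas low vs high tier: rank-sum p = 3.1e-50
4 of 5 marks peak at HighE_LowM; K36-like mark peaks at HighE_HighM
hotspot_fraction_HighE_LowM      39.1%
class accuracy 1.000 | delta bias +0.0002 | delta RMSE 0.0164
```

The qualitative structure mirrors the published biology: methylation
correlates positively with expression, exon–flank deltas are larger at low
expression, most histone marks peak at highly expressed hypomethylated exons
with an H3K36me3-like mark as the programmed exception, and open-chromatin
overlap concentrates in the hypomethylated high-expression set.

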