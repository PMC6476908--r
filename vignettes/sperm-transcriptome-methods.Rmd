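---
title: "Profiling a fragmented sperm transcriptome: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling a fragmented sperm transcriptome: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermkit)
```

## Why element-level quantification

Mature spermatozoa carry very little RNA, and what they carry is heavily
fragmented: most transcripts are represented by short stretches of a few
exons rather than full-length molecules. Whole-transcript quantification
averages coverage over bases that are simply absent, so this package works
instead with *sperm RNA elements* (SREs): short genomic intervals defined
directly by clustered read coverage, quantified and classified on their
own. Around that core sit the companion analyses such a profiling study
needs: a transcript-integrity score, cross-sample stability classes,
repeat-element and lncRNA composition, de novo piRNA cluster detection,
and a two-season differential-abundance test.

## The SRE caller

Reads from all samples are pooled (one coordinate system for the cohort),
merged into maximal intervals in which consecutive reads are separated by
at most `max_gap` uncovered bases (default 0, i.e. contiguous coverage),
and an interval is emitted iff its peak pooled per-base coverage reaches
`min_support` (default 3 reads). Both knobs are exposed because no single
clustering rule is canonical; the defaults are the simplest rule that turns
"reads clustering to a location" into disjoint, sorted, reproducible
intervals. The caller is verified against a brute-force per-base coverage
scan on randomized instances for every parameter combination the tests
exercise.

Quantification is per sample: a read counts toward an SRE when it overlaps
it by at least one base, and RPKM uses the sample's *declared* total mapped
count as denominator (the records handed to the caller may be a filtered
subset of that denominator). Classification precedence is
EXON > NOVEL_INTRONIC > UPDOWN10K > ORPHAN with a 10 kb up/downstream
window; all genes satisfying the winning rule are linked, so one element
can name several genes (adjacent or overlapping loci, e.g. mitochondrial
gene blocks). Overlaps are unstranded by default because library
strandedness is not something the element caller should assume; a
`stranded` flag is available.

Deciles are assigned over elements ranked by mean abundance (decile 1 most
abundant), with ties broken deterministically by position, and the share of
total read mass per decile is reported. Orphan elements get their nearest
gene distance, with the fraction within 30 kb reported inclusively.

## Transcript integrity

For a transcript with per-base exonic depths $c_i$ over $L$ bases, with
$p_i = c_i / \sum c$ over covered bases and $H = -\sum p_i \log p_i$,

$$\mathrm{TIN} = 100 \cdot \exp(H) / L.$$

$\exp(H)$ is the effective number of covered bases, so uniform coverage of
a fraction $f$ of the transcript scores exactly $100f$: 100 means fully and
uniformly covered, 0 means uncovered. We compute it over every exonic base
with no position subsampling — the subsampling some reference
implementations use trades determinism for speed, and at desk scale the
exact computation is fast. The score is invariant to depth scaling and, for
a fixed number of covered bases, maximized by uniform coverage.
Fragmentation classes split at TIN 25 (inclusive, "fragmented") and 75
(exclusive, "intact"). Transcripts with zero coverage are kept at TIN 0;
any `fpkm > 0 & tin > 0` filtering is applied downstream, not inside the
operation.

## Stability, enrichment, over-representation

The coefficient of variation (sample SD over mean, $n-1$ denominator —
cohorts of ten samples are the target scale) is computed on normalized
abundances; classes split at 0.25 and 0.75 with both boundaries assigned to
"moderate" (the interval is read inclusively). A gene inherits a class only
when *all* its elements agree; anything mixed is "unassigned" — a
deliberately conservative rule so gene-level statements are robust.

The tissue-enrichment partition assigns a feature to testes, sperm, or
seminal fluid when it exceeds 40 FPKM there and stays below 10 FPKM in the
other two fractions (strict comparisons on both sides); everything else is
unassigned. Group variability comparisons use one-way ANOVA with Tukey HSD
pairwise p-values. Over-representation of gene sets is an upper-tail
hypergeometric test against a user-supplied GMT collection with Bonferroni
correction over the number of sets tested — the statistical skeleton of the
usual GO tools, without their bundled term databases.

## Small RNAs

Counts are CPM-normalized against per-sample depth. miRNA-style features
pass only if detected (count > 0) in every sample. De novo piRNA clusters
are called per sample from reads of 26-33 nt (inclusive; read length equals
interval length for BED input), merged at a maximum inter-read gap of
1,000 bp, and kept when the span reaches 5 kb with at least 10 supporting
reads. The merge-and-threshold rule replaces the probabilistic density
model of dedicated piRNA callers with two declared knobs; the cluster
caller is oracle-checked like the SRE caller. Consensus clusters are groups
of per-sample clusters overlapping by at least 1 bp (transitively;
book-ended intervals do not count as shared) present in at least 3
samples; the consensus span is the union of its members.

## Seasonal differential abundance

Normalization uses median-of-ratios size factors (geometric-mean
pseudo-reference over features with no zero, factors rescaled to geometric
mean 1). Dispersion is estimated per feature by a small-sample-corrected
method of moments on normalized counts,
$\hat\alpha = (s^2 - \mu) / (\mu^2 - s^2/n)$, computed within season
groups and pooled with $n_g - 1$ weights, then shrunk 50% toward the
median raw estimate of the feature's abundance decile. Three choices here
deserve a note:

* **Within-group moments.** Marginal moments confound a genuine
  between-season effect with biological dispersion, which costs most of
  the test's power precisely on the features of interest (measured
  sensitivity for planted 4-fold changes roughly triples with within-group
  pooling).
* **The corrected denominator.** The plain moment estimator is biased
  downward by roughly 13% at five samples per group, which makes null Wald
  p-values visibly anticonservative; the corrected denominator (floored at
  $0.1\mu^2$ so an extreme variance cannot flip its sign) restores
  near-uniform null p-values.
* **Trend shrinkage.** A 50/50 blend with the abundance-decile median
  stabilizes the very noisy per-feature estimates without flattening real
  mean-dispersion structure.

Each feature is then fitted with a log-linear negative-binomial GLM
(intercept, batch indicator, season indicator; log size factors as offset)
by IRLS at fixed dispersion, and the season coefficient is tested with a
Wald statistic against the standard normal; its estimate is reported as
log2 fold change of summer relative to winter. Features that fail to
converge within 50 iterations are flagged with p = 1 rather than silently
dropped. BH step-up q-values and the significance rule q < 0.05 with
absolute fold change above 1.5 (i.e. $2^{|\mathrm{log2fc}|} > 1.5$, so
strong down-regulation passes the same bar as up-regulation) complete the
pipeline. This estimator chain is deliberately simple and fully testable;
it is not claimed to be numerically equivalent to the empirical-Bayes
machinery of the large DE packages, though its fold-change estimates track
one of them to correlation > 0.99 in the cross-check test.

## The synthetic cohort

Every stage is tested against data with known ground truth from the
generator, driven by one `sim_config()` and one seed (each generator uses
a fixed substream offset, so results are byte-identical across runs).

* **Genome and annotation:** non-overlapping multi-exon genes
  (default 120 genes, three exons of ~500 bp, across four 2 Mb
  chromosomes), 10% flagged lncRNA, repeat intervals scattered per class
  to a configurable genome fraction.
* **Abundance:** per-gene log-normal, `meanlog = log(30)`,
  `sdlog = 1.9`. The tail is calibrated at the *pipeline* level so that
  the top decile of called elements carries about 65% of the read mass —
  the hallmark concentration of sperm transcriptomes. Gene-level theory
  alone would suggest a lighter tail, but reads split over several
  elements per gene and the support filter trims the low tail, both of
  which dilute the top decile; the default reproduces the ~65% share as a
  mean over cohorts, while any single small cohort is noisy because the
  share hinges on the heaviest one or two draws.
* **Fragmentation:** each transcript gets a covered window equal to a
  Beta(1, 3) fraction of its exonic span (≈58% of transcripts below TIN
  25, ≈1.6% above 75, matching the observed preponderance of heavy
  fragmentation). Reads are placed uniformly with wrap-around at the
  window edge, so within-window coverage is exactly flat and TIN has the
  closed form $100f$ — the generator trades the edge ramps of real
  libraries for an exact ground truth. Window *position* is re-drawn per
  sample while $f$ is shared, giving the concordant cross-sample TIN
  profiles real cohorts show.
* **Counts:** negative binomial with log-normal base means, dispersion
  0.2 (typical of bulk RNA-seq), a multiplicative batch effect (default
  1.3) on a batch label alternating within season, and planted
  summer/winter log2 fold changes. Five samples per season.
* **Small RNAs:** 26-33 nt reads concentrated in planted clusters
  (default two clusters of 8 kb, ~600 reads each per sample), 22 nt reads
  at planted miRNA loci, sparse mixed-length background.

What the generator does *not* emulate — spliced reads crossing element
boundaries, positional coverage biases, sequencing error, multi-mapping,
adapter artifacts — bounds what green tests mean: they certify the
algorithms against their definitions and against planted truth, not
robustness to every artifact of real libraries.

## Numerical and degenerate-input conventions

* Intervals are `GRanges` in the 1-based closed Bioconductor convention
  throughout; BED-style readers and writers convert at the boundary, so no
  module ever mixes conventions.
* Decile ties break by (abundance, chromosome, start) — deterministic
  under permutation of the input.
* An empty read file is a valid, empty sample; a zero depth denominator is
  an error, never an Inf.
* CV with mean 0, correlation with zero variance, and deciles with fewer
  than ten elements are reported as NA/flagged/error respectively rather
  than silently coerced.
* GLM non-convergence yields p = 1 with a flag; all-zero features are
  excluded from dispersion estimation and testing.
* Problem sizes in the shipped tests (120-gene cohorts, 2,000-feature
  count matrices, 20-seed replication for the FDR and sensitivity
  properties) were chosen as the smallest cohorts at which the
  heavy-tailed quantities of interest are stable.

## Known limitations

The element caller is not splice-aware: a read spanning an intron
contributes two disjoint blocks only if the aligner already split it. The
dispersion estimator, while calibrated, has no empirical-Bayes sharing
beyond the decile trend, and at fewer than three samples per group it
should not be trusted. piRNA cluster calling ignores strand and ping-pong
structure. The tissue-enrichment partition requires externally supplied
reference FPKM values; none are bundled.
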