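---
title: "Benchmarking peak and fragment sets: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking peak and fragment sets: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peakbench)
```

## The problem

Low-input chromatin profiling assays (CUT&Tag and relatives) are validated
by comparison against an established reference — typically consortium
ChIP-seq peak sets for the same histone modification. That comparison is a
retrieval problem over genomic intervals: which reference peaks does the
new assay capture, at what false-positive cost, and does it preferentially
capture the strongest reference signal? `peakbench` implements the
statistics of that comparison, the fragment-level quality metrics that
accompany it, and a synthetic generator that makes all of it testable with
known ground truth on a desk-scale genome.

## Capture model

All coordinates are 0-based, half-open (BED). Two intervals overlap when
they share at least `min_bp` bases (default 1 bp, strand-agnostic — the
default of the standard interval tooling; half-open adjacency is not an
overlap). For a query set $Q$ and reference set $R$:

* $tp$ — query peaks overlapping at least one reference peak,
* $fp = |Q| - tp$,
* captured — reference peaks overlapped by at least one query peak,
* $fn = |R| - \mathrm{captured}$,

with precision $tp/|Q|$, recall $\mathrm{captured}/|R|$, and

$$F1 = \frac{tp}{tp + \tfrac{1}{2}(fp + fn)}.$$

True negatives are excluded: un-peaked genome dominates and would swamp
any score that counted it. Two asymmetries are resolved deliberately. A
query peak hitting two reference peaks counts once toward $tp$, and each
reference peak counts once toward captured: both metrics are proportions
of peaks, so neither side is double-counted. And because $tp$ is
query-side while $fn$ is reference-side, F1 equals $2PR/(P+R)$ exactly
only when the query-side and reference-side capture counts coincide; the
reference-side count is always reported separately so recall is never
distorted. When reference peaks are adjacent, capture is counted on the
peak records as read from file, not on merged intervals.

Coverage-matched capture makes peak sets of different breadth comparable:
query peaks are ranked by `signal_value` (falling back to `score`,
position as tie-break) and accumulated until their total width first
reaches a base budget; the peak crossing the budget is kept whole, since
splitting a peak record would manufacture intervals no caller emitted.

## Fragment metrics

The unit of all fragment metrics is the fragment, not the read —
paired-end reads are two views of one fragment, and `read_multiplier`
affects only the reported `mapped_reads`. Two membership rules coexist:
"reads in peaks" metrics (FRiP, cross-mark specificity, density
enrichment) count a fragment when it overlaps the merged region set by at
least 1 bp, while binned counts and anchor-centered matrices assign each
fragment to exactly one bin by its midpoint, which keeps totals conserved
across bins. Duplicates are fragments with an identical
(chromosome, start, end) span; the first occurrence stays unflagged, the
duplication rate is the flagged fraction in percent, and marking is
idempotent.

The fingerprint curve ranks fixed-size bins (default 1,000 bp) by count
and reports cumulative counts along the rank order. The default
normalization divides by the count of the single highest bin — the
definition we adopt for the headline curve — with the conventional
fraction-of-total normalization available via `mode = "total"`; the two
differ only by a constant factor (total/max), so the curve shape is
identical. Quantile normalization of binned counts is the classical
procedure (each sample's order statistics replaced by cross-sample means;
tied ranks receive the mean of the tied positions) via
`limma::normalizeQuantiles`, followed by round-half-to-even to integers.
Note that tie-averaging means exact equality of sorted sample vectors
holds only for tie-free data; with the zero-inflated counts of sparse
samples, sorted vectors agree only up to the tie groups.

Welch's unequal-variance t-test (two-sided only, as is standard for
stratified peak comparisons) backs the captured-vs-missed contrasts; no
multiple-testing correction is applied because each stratification is a
single pre-specified test. The qPCR helper computes
$2^{-(\mathrm{Ct}_{sample} - \mathrm{Ct}_{control})}$ per replicate and
summarises triplicates by mean and sample SD on the linear fold-level
scale (the scale on which such screens are plotted); SD on the
$\Delta$Ct scale would be the alternative had the convention been
otherwise.

## Filtering rules

Blacklist filtering removes peaks overlapping any blacklisted interval by
at least 1 bp; it is applied to peaks (fragment filtering is available as
an option but not applied by default). Chromosome filtering keeps an
explicit allow-list, dropping mitochondrial and non-standard contigs.
Fragment-length filtering keeps $min \le w < max$: "under 1,000 bp" is
read as exclusive, and the sub-100 bp exclusion (`min_bp = 100`) keeps a
width of exactly 100. Off-layout records in input files are dropped with
a warning by default (real peak files routinely carry alt contigs), with
a strict mode that errors instead.

## The synthetic generator

The generator's defaults are the emulated study conditions and are not
tuned per analysis:

| parameter | default | rationale |
|---|---|---|
| genome | 3 × 2 Mb | large enough for 1,000 well-separated peaks, small enough for per-base oracles |
| reference peaks | 1,000, ≥ 1 kb gaps | typical dense-mark peak counts scaled to the toy genome |
| peak widths | lognormal, median ≈ 800 bp, sdlog 0.45 | narrow-mark reference peak widths |
| `-log10(q)` | 2 + Exp(rate 0.2) | heavy right tail above a significance floor, as in reference peak lists |
| capture model | logistic in `-log10(q)`, intercept −2, slope 0.5 | the simplest monotone model of "the most significant peaks are captured"; its truth is recoverable |
| boundary jitter | SD 50 bp | caller boundary noise, small against peak width |
| false query peaks | 200 | a visible but not dominant false-positive load |
| fragments | 20,000; FRiP 0.40; duplication 60% | a mid-quality sample where both targets are stringent to recover |
| lengths | 0.8 · N(180, 25) + 0.2 · N(60, 15), ≥ 20 bp | nucleosomal mode plus a sub-100 bp population |

Reference peaks are placed uniformly conditional on non-overlap with
≥ 1 kb gaps (the spacings construction, so placement is exactly uniform
over feasible configurations). Peak width and significance are drawn
independently — the realistic joint distribution is unknown, and
independence keeps the ground truth simple. Captured query peaks always
still overlap their source peak (jitter ≪ width), and false peaks are
rejection-sampled to avoid the reference entirely, so the generator's
capture flags are exactly the overlap truth: `capture()` recall equals
the realised capture rate and precision equals
captured/(captured + false). Signal fragments have their midpoint uniform
inside a width-weighted random peak (optionally biased toward a designated
"accessible" subset, emulating open-chromatin bias of
transposase-based assays); background fragments are rejection-sampled to
avoid peaks entirely, so the realised FRiP is the in-peak fraction
exactly, a binomial draw around the target. Duplicates are uniform
resamples of existing fragments — preferential duplication of short
fragments is deliberately off by default, since short-fragment abundance
is not a duplication artifact in this assay class — and the base
fragments are kept pairwise distinct, so the measured duplication rate
equals the resampled fraction up to rounding.

What the generator does not emulate: sequence content and mappability,
GC bias, alignment error, spike-ins, and realistic correlation structure
between replicate samples. Tests passing on synthetic data therefore
establish that the metrics measure what they claim on inputs with known
truth — not that any particular real assay will score well.

The plumbing peak caller (`threshold_peak_caller`) exists to exercise
threshold sweeps end-to-end: it keeps bases whose coverage reaches the
`1 − top_fraction` quantile of nonzero step values and merges contiguous
runs. It is intentionally naive — a stand-in for real callers in
synthetic runs, not a peak caller for real data, and real callers' sweeps
are not assumed nested or monotone anywhere in the code.

## Numerical choices

Quantile ties average; rounding is half-to-even. Sorting is by
chrom.sizes order, then start, then end, everywhere. Downsampling and all
generators draw from R's default RNG under an explicit seed, restoring
the caller's RNG state afterwards; every stochastic operation takes the
seed explicitly. Degenerate inputs follow a warn-or-error policy:
undefined ratios (empty reference → recall, no fragments in either mark →
specificity, constant occupancy → correlation) return NaN with a warning;
empty required inputs error.

## Problem sizes

The shipped tests run the oracle comparisons on ≤ 400 random peaks per
instance over 400 kb toy genomes, parameter recovery over 20 seeds at the
default conditions, and the stratification direction check over 100 seeds
at 500 reference peaks — sizes at which the brute-force per-base and
all-pairs oracles are exact and fast, and the statistical checks have the
power the invariants claim (e.g. captured-vs-missed direction in ≥ 95% of
runs at logistic slope 1.5).

## Limitations

Capture is count-based, not base-pair-resolution: reciprocal-overlap and
Jaccard statistics are out of scope, as are strand-aware overlap, BAM
ingestion (fragment BED is the canonical input), bigWig/bigBed, motif and
gene-ontology analyses, and peak-caller re-implementations. The promoter
machinery supports both ±1.5 kb and ±3 kb window conventions as
parameters; neither is privileged, because both are in common use for
different analyses.
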