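---
title: "SNP-array karyotyping and MAR discovery: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SNP-array karyotyping and MAR discovery: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marscan)
```

`marscan` reconstructs tumor karyotypes from per-probe SNP-array signal
and mines cohorts for recurrent lesions. This vignette documents the
models behind each stage, the tunable parameters with their defaults and
units, the numerical conventions, and the design choices that were
genuinely open — the material a maintainer needs before changing
anything.

## Signal model and the synthetic cohort

A probe reports a log-R ratio (LRR) and, for SNP probes, a B-allele
frequency (BAF). The generator (`simulate_sample()`) realizes the
standard model:

* expected LRR is $\log_2(\mathrm{CN}/2)$ for total copy number CN, i.e.
  0 for the diploid baseline, $+1$ for CN 4, $-1$ for CN 1. A CN of 0
  has no finite log, so it is floored at $-5$ — homozygous deletions are
  not a focus and the floor only guards the arithmetic;
* with tumor purity $p$ (default 1), the mixture expectation is
  $\log_2\!\big((p\,\mathrm{CN} + (1-p)\,2)/2\big)$. Purity is exposed
  but defaulted to 1; subclonality is out of scope;
* BAF sits at $n_B/\mathrm{CN}$ where $n_B$ is the B-allele copy count.
  Germline heterozygotes are drawn per SNP probe as Bernoulli(0.3)
  (exchangeable across probes — a simplification; real heterozygosity
  tracks allele frequency and LD). Under LOH one parental allele is lost
  entirely; under a non-LOH gain all extra copies derive from one
  randomly chosen allele. aUPD is CN 2 with LOH: flat LRR, heterozygous
  BAF displaced to 0/1;
* noise: Gaussian on LRR (sd 0.2 by default, a mid-range value for
  6.0-class arrays) and truncated Gaussian on BAF (sd 0.03, clipped to
  [0, 1]). Genotype calls are banded from the noisy BAF.

The default cohort (`default_config()`) is desk-scale: 4 autosomes ×
10 Mb at 1 kb spacing (~40k probes/sample, 20 tumor/normal pairs), which
keeps a full run under half a minute while preserving ≥10-marker lesions
down to 10 kb. Coordinates are 1-based half-open throughout, so
`length = end - start` reproduces published interval arithmetic, and BED
export subtracts 1 from both bounds.

Two generator choices deserve emphasis. First, `private_lesion_rate` is
an exact per-sample count, not a Poisson mean: truth-table bookkeeping
(carrier counts, recurrence ground truth) stays deterministic. Second,
private lesions avoid the shared locus in *every* sample: a "private"
lesion landing on the shared locus in a non-carrier would silently raise
the locus recurrence above the implanted carrier count, making the truth
table wrong about the one quantity the MAR stage is meant to recover.

What the generator does *not* emulate: GC waviness and other intensity
artifacts (vendor preprocessing removes them on real arrays), genotyping
error, allele-frequency structure, subclonal mixtures, sex chromosomes.
Passing tests therefore demonstrate correctness of the algorithms under
the stated noise model, not robustness to every array pathology.

## Segmentation

`segment_series()` is recursive top-down binary splitting. For a region,
the candidate breakpoint maximizes the pooled-variance two-sample t
statistic between left and right probe values (prefix-sum scan, leftmost
tie-break for determinism); the split is accepted iff both sides retain
`min_markers` (default 10) probes and the two-sided t p-value is at most
`split_alpha` (default 0.001). Accepted halves are recursed. Afterwards
adjacent segments whose means do not differ at `merge_alpha` (default
equal to `split_alpha`; the most-similar pair merges first) are
re-merged. When the pooled variance is zero the statistic is taken as
±Inf (p = 0) for unequal means and 0 otherwise, which handles noise-free
data exactly.

The global binary split has a known blind spot: a short lesion in the
middle of a long flat region contributes almost nothing to the
difference of half-means (a 50-marker, one-copy gain centered in 10,000
probes moves the global t to ≈ 1). When the global split is rejected,
a windowed scan compares the `w` probes on either side of every cut at
scales `w ∈ {10, 20, 40}` markers; because the scan maximizes over ~n
dependent statistics, its p-value is Bonferroni-corrected by the number
of cuts per scale before being compared with `split_alpha`. Without the
correction, noise segments of |mean| ≈ 0.3 pass; with it, the false
discovery rate is negligible while 20-marker single-copy gains remain
comfortably detectable (window t ≈ 6.6). The global test is left
uncorrected, as its statistic is diluted rather than maximized over
short windows.

`mask_low_density(max_gap = 100 kb)` splits the series at inter-probe
gaps strictly greater than `max_gap` so no segment spans a marker
desert, and flags sub-`min_markers` fragments as excluded. The boundary
is strict (a gap exactly equal to `max_gap` does not split). 100 kb is a
configurable default; the filter exists to mimic the exclusion of
low-marker-density regions, for which no published number exists.

Segment bounds snap to member probes: `start` is the first probe
position and `end` the last probe position + 1. Two consequences: a
segment's coordinates never extend beyond observed markers, and two
adjacent segments are separated by a marker-free hole of roughly one
probe spacing (see the MAR bridging note below).

## Lesion classification and filters

`call_cn_state()` maps mean segment LRR to
`cn_estimate = 2·2^mean_lrr` (one decimal) and to a state via
`gain_threshold = +0.15` / `loss_threshold = -0.2`. The thresholds are
deliberately asymmetric: on the log2 scale a one-copy gain is +0.58 but
a one-copy loss is −1, so the loss cut-off can afford to be farther from
0. No calling cut-offs are published for the original analysis; these
defaults are conventional and configurable.

`call_loh()` counts informative SNPs — heterozygous in the matched
normal (paired mode), or heterozygous in at least half the reference
panel (baseline mode, a population proxy explicitly documented as lower
confidence) — and calls LOH when ≥ 90% of them show tumor BAF in the
homozygosity bands (≤ 0.1 or ≥ 0.9). Segments with fewer than 10
informative SNPs are annotated "uninformative" and get `loh = FALSE`;
10 mirrors the segmentation marker floor.

`classify_five_state()` is the total map from (state, LOH) to
{AMP_LOH, AMP_NO_LOH, AUPD, DEL_LOH, DEL_NO_LOH, NEUTRAL}; NEUTRAL
(copy-neutral, no LOH) is not a lesion and is dropped.

Copy-neutral LOH needs its own discovery route: an aUPD region produces
no LRR step, so LRR segmentation never isolates it and a whole-arm
neutral segment would dilute its homozygosity fraction below any
threshold. `detect_aupd()` therefore segments the *mirrored BAF*
(`|BAF − 0.5|`; ≈ 0.024 expected under retained heterozygosity at
BAF sd 0.03, ≈ 0.5 under LOH) of the informative SNPs with the same
splitter, and reports segments with mean mirrored BAF ≥ 0.35 whose mean
ratio LRR stays inside the copy-neutral band as AUPD lesions.
`call_sample_lesions()` runs both routes and drops aUPD calls that
collide with an LRR-derived lesion.

`apply_filters()` applies, in order: excluded chromosomes (X, Y, MT by
default; "chr" prefixes ignored), CNV length < 1 kb, aUPD length < 1 Mb,
and blacklist cytobands (defaults "7p34", "7p14.1", "14q11.2" — the
T-cell-receptor artifact bands of a T-lymphocyte reference). Blacklist
names are matched verbatim against the user's cytoband map: "7p34" is
not a band in UCSC nomenclature (the TRB locus sits on 7q34), so it
simply never fires unless the map defines it; both spellings are
accepted in configuration and the test suite exercises the 7q34 variant.
Every rejection is logged with its rule, and filtering is idempotent.

## Cohort recurrence and the MAR

`define_mar()` computes, per chromosome, the count of *distinct* samples
affected at every position: lesions are unioned per sample, then a
sweep-line over interval endpoints accumulates +1/−1 events. Candidate
regions are maximal constant-count runs whose support strictly exceeds
`cohort_size × min_fraction` (default 0.5 — a strict majority, so 11/20
qualifies and 10/20 does not). The MAR is the candidate with the highest
support. Ties break to the *longest* run, then genomic order: trimming
to the majority-support run is what makes the region "minimal"; among
equally supported runs, preferring the shortest would let a kilobase
sliver created by one sample's fragmented call displace the consensus
region (observed in simulation), while the widest equally-supported run
is the consensus. The mean copy number averages `cn_estimate` over the
supporting samples' overlapping lesions; all candidates are returned.

Because segment bounds snap to probes, two same-sample lesions can be
separated by a hole of about one probe spacing that contains no marker
at all. Such holes are not evidence of interruption, and they fragment
majority runs. `define_mar()` and the interval-unit
`recurrence_profile()` accept `bridge_gap` (bp): per-sample gaps up to
it are closed before counting. The default is 0 — exact per-base
semantics, under which the sweep-line provably matches a brute-force
per-base count (property-tested on random mini-cohorts) — and the
pipeline passes 2 × probe spacing.

`chromosome_density()` normalizes lesion counts by chromosome length in
Mb and tests the raw counts against a length-proportional expectation
with `chisq.test` (df = #chromosomes − 1; single-chromosome input
returns p = NA). `overlap_significance()` treats two cytoband sets as a
draw of |B| bands from a universe with |A| marked and reports the
upper-tail hypergeometric p for the observed intersection, with the
percentage relative to A. The universe is user-supplied: the appropriate
universe (all bands? autosomal bands of the map in use?) depends on the
study design, so no default is imposed and no attempt is made to match
any particular published p-value, whose universe is unknown.

## Calibrator-free qPCR copy number

Each duplex well yields ΔCt = Ct(target) − Ct(reference); per sample,
`aggregate_wells()` computes the replicate mean and the n−1 standard
deviation, with QC at σΔCt < 0.15 (strict inequality). At least two
replicates are required; the bundled plates use four. Without a
calibrator sample, `copy_number_no_calibrator()` anchors the scale at
the median mean-ΔCt of QC-passing samples and assumes that anchor
represents `reference_cn = 2` copies (the reference assay is diploid):
`cn = 2·2^(anchor − ΔCt)`, rounded for the integer call. The median
anchor is valid only when more than half the plate is copy-neutral at
the target — which is why the pipeline's validation plate includes the
matched normals alongside the tumors, mirroring a plate design with
non-neoplastic controls. `concordance()` reports the fraction of samples
where array and qPCR agree on "amplified" (integer CN ≥ 3 by default),
both over all samples and restricted to QC passes, since whether
QC-failing samples should count is a judgment call.

## Numerical conventions and degenerate inputs

* Coordinates: 1-based half-open internally; UCSC cytoBand and BED are
  converted by ±1 on both bounds (lengths preserved).
* Determinism: every stochastic routine takes a seed; identical
  (configuration, seed) reproduce outputs byte-for-byte. Tie-breaks
  (leftmost split, most-similar merge first, longest-then-leftmost MAR)
  are all deterministic.
* Degenerate inputs: series shorter than `min_markers` segment as a
  single block with a warning, never an error; an empty known-variant
  database annotates everything novel with a warning; a cohort with no
  majority region returns an explanatory status, not an error; readers
  reject malformed files (unsorted probes, BAF outside [0, 1], schema
  mismatches) with line numbers rather than coercing.

## Problem sizes used by the checks

The test suite and the acceptance script run the full pipeline on the
default 20-sample, 4 × 10 Mb, 1 kb-spacing cohort (~1.6M probe records
across tumors and normals; ≈ 30 s), oracle comparisons on 100 random
series of ≤ 200 probes and 100 random mini-cohorts of ≤ 10 samples on a
≤ 10 kb genome, zero-noise classification cohorts on 2 × 5 Mb genomes,
and 4-replicate qPCR plates. These sizes were chosen so a complete run
is a coffee-break affair on one core while every lesion class and code
path is exercised.

## Known limitations

* LRR-only segmentation plus the mirrored-BAF aUPD route assumes pure,
  clonal tumors; at purity well below 1 the homozygosity bands blur and
  the 0.35 mirror threshold loses power (the purity parameter exists in
  the generator precisely to study this).
* Baseline (unpaired) LOH is a population proxy and over-calls where the
  panel happens to be heterozygous but the case is germline-homozygous.
* The known/novel rule (≥ 50% of the lesion covered by database
  intervals) is a convention, not a published criterion; it is
  configurable and logged.
* No GC-wave correction, no amplification-efficiency correction for
  qPCR, no gene-level annotation beyond user-supplied intervals.
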