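---
title: "Methods: miRNA microarray analysis of MSCs across culture passages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA microarray analysis of MSCs across culture passages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirpassage)
```

## The problem

Bone-marrow-derived multipotent stromal cells (MSCs) must be expanded in
culture before therapeutic use, and their properties drift with passage
number. This package implements an analysis pipeline for single-color miRNA
microarray experiments designed to ask which miRNAs are (a) consistently
expressed across donors and passages and (b) differentially expressed
between early and late passages, on a repeated-measures design: several
donors, each measured at passages P3/P5/P7, each passage hybridized on three
technical-replicate arrays, and each probe sequence spotted 4–8 times per
array. An RT-qPCR arm confirms candidate miRNAs on independent MSC sets.

Everything runs on synthetic data with known ground truth, so the pipeline's
operating characteristics (false-discovery control, detection calibration,
fold-change recovery) are measurable without any external download. Real
probe-level tables (a minimal Agilent Feature Extraction-like dialect) and
GEO series-matrix-style processed tables can be read through `read_probe_table()`.

## Signal model and normalization

Probe signals are modelled additively on the log2 scale:

$$ y_{spda} = \beta_s + u_{sd} + \tau_{sp} + a_a + \varepsilon $$

with sequence baseline $\beta_s$, per-(sequence, donor) random effect
$u_{sd}$, passage effect $\tau_{sp}$, array offset $a_a$, and probe noise
$\varepsilon$. The generator exponentiates ($2^y$) to a raw-intensity scale
so that log2 of the raw signal recovers the additive model; raw intensities
are treated as lognormal, the usual working assumption for array signals
(the distribution family is not dictated by the design).

Probe replicates are collapsed to one value per (sequence, array) by the
median on the raw scale, robust to single-spot artifacts. Two normalization
schemes are provided:

* `quantile_normalize()` — cross-array quantile normalization of the raw
  signal with no background correction. The reference distribution is the
  mean of order statistics across arrays; tied values receive the mean of
  their tied ranks' reference values (the standard convention; the method is
  idempotent and column-order invariant). This is the default downstream
  input.
* `afe_tgs_p75()` — vendor-style total-gene-signal scaling: each array is
  scaled so its 75th percentile equals the geometric mean of all arrays' 75th
  percentiles. The scaling target is a free constant; any fixed choice
  cancels in downstream differences, and the geometric mean keeps the output
  centered on the input distribution.

Whether probe replicates are collapsed before or after normalization is a
genuinely open choice; the pipeline collapses first (the collapsed matrix is
what the downstream statistics consume and the within-array median is
normalization-invariant up to monotone maps), and `within_chip_cutoffs()`
accepts externally normalized probe-level values for the alternative.

## Detection and outlier arrays

Each array carries negative-control probes (434 in the default design).
The background cutoff for a donor/passage group is the mean + 1 SD of the
pooled negative controls of that group's technical-replicate arrays
(3 × 434 values): "a specific donor/passage" spans its triplicate, so the
pooled version is used rather than averaging per-array cutoffs (both are one
switch apart in `background_cutoffs()`). A sequence is *expressed* in a
group when its median over the group's technical replicates exceeds the
group cutoff, and *commonly expressed* when that holds in every group. The
miRNA-level roll-up excludes sequences reclassified as tRNA/rRNA (an input
annotation flag) and calls a miRNA commonly expressed when at least one of
its sequences is.

Arrays with extremely elevated background are flagged before any analysis:
an array is an outlier when its mean log2 negative-control signal exceeds
the median + k·MAD (k = 5 by default) of the per-array means. The rule is a
deliberate formalization of "extremely elevated"; k·MAD on per-array means
is robust to the small number of affected arrays, and `k` is configurable.

## The four-stage filter cascade

Differences between the endpoint passages are only meaningful when they
exceed what technical replication can produce, so sequences pass four
ordered stages (`apply_cascade()`):

1. **Within-chip**: per sequence, the SD across an array's probe replicates
   (sample SD, n−1) is computed per array; the cutoff is the median over
   arrays. The endpoint contrast |mean over donors of (late − early)| must
   strictly exceed it.
2. **Between-chip**: the same contrast against the median over donor/passage
   groups of the SD across that group's technical-replicate arrays. This
   definition is a reconstruction — the replicate-array SD is the only
   replication axis left once within-array variance is taken by stage 1 —
   and is isolated in `between_chip_cutoffs()` so an alternative formula is
   a one-line swap.
3. **Biological variability**: a paired t-test of the per-donor early/late
   means; p ≤ 0.05 keeps (inclusive at the boundary; configurable).
4. **Magnitude**: the mean expression at every passage must exceed the
   global negative-control cutoff, taken as mean + 1 SD of the pooled
   negative controls of all arrays, consistent with the detection
   convention (a mean-only switch is provided).

Only donors observed at both endpoint passages enter the contrast; donor
level values are means over technical replicates. A sequence failing stage
*i* has later stages recorded as not-evaluated (`NA`), and the per-stage
elimination counts always sum to the total (a tested invariant, as are
order-invariance and monotonicity under cutoff tightening).

## Repeated-measures ANOVA with compound symmetry

For eligible sequences, log2 expression is modelled against passage with a
compound-symmetry correlation structure within donors — every pair of
passages of a donor equally correlated. The model is fitted by REML with
`nlme::gls(..., correlation = corCompSymm(~ 1 | donor))` rather than a
donor random intercept: the CS parameterization admits the small negative
within-donor correlations a variance-component parameterization truncates,
which is what keeps the classical equivalences exact. Technical replicates
are averaged to donor/passage units first — the repeated measure is the
donor, and leaving technical replicates in the residual would overstate the
degrees of freedom.

Pairwise passage contrasts are tested with containment degrees of freedom
$(n_\text{donors}-1)(n_\text{passages}-1)$; in the balanced two-passage
special case the contrast test is exactly the paired t-test (verified to
1e-5 relative, the REML optimizer's precision). When the GLS fit fails
(e.g. zero residual variance in degenerate fixtures) the implementation
falls back to the closed-form paired contrasts and says so in the result's
`method` column.

Benjamini–Hochberg adjustment is applied per contrast family across
sequences (one family per pairwise comparison), since results are reported
per contrast; pooling all contrasts into one family is available via
`adjust_scope = "pooled"`. Significance is adjusted p < 0.05. Fold changes
use the signed convention `d ≥ 0 → 2^d`, `d < 0 → −2^(−d)`.

The MSC-versus-cancer comparison (`pooled_t_group_contrast()`) uses the
classic unequal-sample-size, equal-variance pooled t-test on biological
units (8 donor means vs 2 cancer-sample means), after re-running the
technical and magnitude filters with the group difference in place of the
passage difference. The magnitude stage requires both group means above the
background cutoff, the direct analog of the every-passage rule; this
removes pure on/off markers by design and is configurable.

## RT-qPCR arm

Reference normalization uses the geometric mean of five SNORD reference
targets, computed on the abundance scale — equivalently the arithmetic mean
of their Cq values, since $\mathrm{geomean}(2^{-C_q}) = 2^{-\overline{C_q}}$.
Normalized expression is ΔCq = reference − target (log2 units, increasing
with expression), which cancels any per-sample global shift (a tested
invariant). Detection uses the median Cq across well replicates against a
threshold of 35 cycles; a target with fewer than half its wells amplified is
undetected, and undetected wells are an explicit sentinel, never numeric 0.
Passage tests are paired across matched lines by default (the lines are
matched; an unpaired switch exists); the cross-set test is a two-sample t on
the per-line early-to-late differences, and non-MSC cohorts are compared to
early-passage MSC expression. PPC/miRTC control wells are range-checked but
never used in normalization.

## What the generator emulates — and what it does not

Defaults reproduce the study design: 8 donors × {P3, P5, P7} × 3 technical
replicates with one donor stopping after P3 and one after P5 (63 arrays, 21
donor/passage groups), 2686 sequences for 939 miRNAs with 4–8 probe
replicates, 434 negative controls per array (5.29 ± 0.11 log2), and two
arrays with +3 log2 elevated negative-control background that the outlier
rule should find, leaving 61 analyzable arrays. The expressed set mirrors
the study's composition: 41 duplicate long/short pairs (long 0.74 log2
above short, a 1.67-fold offset), 30 singletons, and 11 tRNA/rRNA-flagged
sequences. Twelve sequences carry passage effects with the study-scale fold
magnitudes (1.05–1.49, both signs), the two strongest on a duplicate pair of
one miRNA. Noise SDs are not dictated by the design and were fixed once at
field-plausible values: probe noise 0.05, array offset 0.05, donor effect
0.15 (log2).

A further *variable* class (~19% of sequences) is expressed at high level
but silenced to near background in one donor per sequence. It serves two
purposes: it reproduces the donor-to-donor heterogeneity such studies
report, and it gives the upper intensity range the dense, continuous rank
structure of real arrays. The latter matters: quantile normalization moves
values by rank, so when spiked sequences change rank between passages,
neighboring null sequences are displaced by (crossings × local rank
spacing). On a sparse synthetic upper tail this displacement can exceed the
technical cutoffs and manufacture consistent pseudo-effects; at the default
density it stays below them. Scaled-down test configurations keep this
density-to-cutoff ratio rather than the raw sequence count.

The generator does **not** model: image-level artifacts or spot
quantification, spike-in ladders, dye bias (single color), probe-sequence
cross-hybridization, intensity-dependent variance (variance is flat in
log2), or amplification-efficiency differences in qPCR. Passing tests
therefore demonstrate the statistical machinery under the stated additive
lognormal model, not robustness to those effects.

## Numerical choices and degenerate inputs

* Quantile-normalization ties: mean of the tied ranks' reference values.
* Zero-variance paired t-tests return p = 0 (nonzero mean) or p = 1
  (all-zero differences) with a degeneracy note, so deterministic fixtures
  do not crash.
* Sequences spotted once per array get within-chip cutoff 0 with a warning.
* Group background cutoffs with zero arrays are excluded from the
  "all groups" quantifier with a warning.
* Single-array matrices pass through normalization as log2 with a warning.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`; the test
  suite checks it against an independently coded step-up oracle.
* PCA (`pca_views()`) centers but does not scale; "supervised" means
  restricting to a provided significant set before the SVD.
* Heatmaps use 1 − Pearson correlation distance with average linkage (no
  metric is dictated; this is the common choice for expression heatmaps and
  is configurable).

## Problem sizes used by the test suite

Unit and property tests run on scaled-down designs (typically 6 donors × 3
passages × 2 replicates, 120–400 sequences) chosen so each block completes
in seconds. The calibration blocks use 50 simulations each: the null
calibration at 150 sequences with no passage effects, and the
false-discovery / recovery block at 1400 sequences with 600 variable-class
sequences — the configuration that reproduces the full design's upper-range
rank density, as discussed above. The acceptance script
(`scripts/acceptance.R`) runs the full-scale default design.

## Known limitations

* The between-chip variability definition is a reconstruction (see above);
  eligible-set counts are sensitive to it.
* Containment degrees of freedom are one convention; small-sample p-values
  under other df conventions (e.g. Kenward–Roger) can differ in the third
  decimal.
* Quantile normalization compresses effects at the extreme top of the
  intensity range (the reference tail is bounded), so recovered folds for
  very strong, very highly expressed spikes are attenuated.
* The filter cascade and the subsequent ANOVA reuse the same endpoint
  contrast, so stage 3 pre-selects sequences the ANOVA will tend to find
  significant; BH adjustment is applied to the post-filter family, as in
  the original procedure, and the null-calibration test bounds the
  resulting overall false-positive rate rather than the post-selection
  error per se.
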