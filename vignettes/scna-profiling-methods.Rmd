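---
title: "Methods: bin-level SCNA profiling of cfDNA from shallow WGS"
author: "csfscna"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bin-level SCNA profiling of cfDNA from shallow WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csfscna)
```

## The problem

Cell-free DNA (cfDNA) in cerebrospinal fluid carries fragments shed by CNS
tumors. Tumor genomes are typically aneuploid, so tumor-derived cfDNA leaves
a copy-number footprint: genomic regions gained in the tumor are slightly
over-represented among sequenced fragments, lost regions under-represented.
Shallow whole-genome sequencing (well below 1x depth) is enough to read this
footprint at the scale of multi-megabase windows, without prior knowledge of
the tumor's mutations.

`csfscna` implements that analysis as a reusable pipeline: per-bin read-pair
counts are corrected for GC content and mappability, normalized by the
median count over all windows, log2-transformed, thresholded into aberrant
bins, and summarized into three sample-level metrics. Because clinical CSF
sequencing data are not freely redistributable, the package also ships a
synthetic-data generator that emulates cfDNA tumor/normal mixtures, so every
stage is exercised end to end by code alone.

## The model

### Binning

The genome (HG19 by default; `hg19_chrom_sizes()`) is tiled into fixed
windows of `bin_size` = 5,500,000 bp. The window step defaults to the bin
size, i.e. non-overlapping tiling. A configurable smaller step gives true
sliding windows, but the default deliberately avoids overlap: overlapping
windows would count the same aberration more than once in the additive score
below. Coordinates are 0-based half-open everywhere except human-readable
report text.

A partial bin remains at most chromosome ends. It is kept in the grid (so
serialization round-trips exactly) but flagged unusable when shorter than
half a bin, because a short bin collects proportionally fewer reads and its
count ratio is noisier. Bins can further be dropped by mappability or GC
range filters or an interval blacklist (`apply_usability_filters()`); a bin
with more than 50% undetermined (N) sequence is never usable.

Sex chromosomes are kept in the grid but excluded from normalization and
scoring by default: the pipeline does not know the patient's sex, and a
male X at half depth would otherwise masquerade as a 23-bin deletion.

### Correction and normalization

Shallow-WGS bin counts carry a smooth bias in GC content and scale with
mappability. `correct_counts()` divides length-normalized counts by a fitted
bias term, normalized to mean 1 over usable bins, with two interchangeable
fits:

* `median_bins` — the transparent reference method: the median
  mappability-adjusted count per GC decile, interpolated linearly between
  decile midpoints, times a linear mappability term. Simple enough to verify
  by hand, used as the cross-check for the smooth fit.
* `loess` (default) — a robust local-quadratic fit (`family = "symmetric"`,
  span 0.5) of mappability-adjusted counts against GC. With fewer than 30
  usable bins a loess fit is not meaningful and the method falls back to
  `median_bins` with a warning.

Corrected counts are divided by the **median** corrected count over usable
autosomal bins and log2-transformed (`to_log2_profile()`). The median (not
the mean) keeps the copy-neutral baseline at log2 = 0 even when a minority
of bins are aberrant. Ratios are floored at 2^-8 before the log so that a
zero-count bin — the signature of a homozygous deletion at high tumor
fraction — contributes a large but finite deletion term instead of -Inf.

### Calls and metrics

A bin is aberrant when its log2 ratio is strictly above +0.1
(amplification) or strictly below -0.1 (deletion); a value exactly at the
threshold is neutral. The strict inequality is applied consistently on both
sides. Three sample-level metrics follow (`compute_metrics()`):

* **CNI score** (chromosomal number instability): the sum of |log2 ratio|
  over aberrant bins.
* **Aberrant-bin count**, with the sample deemed **SCNA-positive** at >= 5
  aberrant bins (inclusive boundary). The 5-bin floor makes a sample
  positive only on evidence no plausible run of per-bin noise produces.
* **Tumor-cfDNA fraction score**: CNI score / aberrant-bin count, i.e. the
  mean aberrant-bin |log2 ratio|. Aberrations in a sample rich in
  tumor-derived cfDNA are less diluted by normal cfDNA, so this score rises
  with tumor content but — unlike the CNI score — does not grow with the
  *number* of aberrations. It is undefined (JSON `null`) when no bin is
  aberrant, and whenever defined it necessarily exceeds 0.1, since every
  contributing bin does.

No segmentation is performed: the published metrics are defined directly on
bins, and a segmentation step would change their values.

### The mixture model behind the simulator

A cfDNA sample with tumor fraction $f$ mixes tumor DNA of integer copy
number $c$ with diploid normal DNA. The expected relative coverage of a bin
with (length-weighted) tumor copy number $c$ is

$$ r(c, f) \;=\; \frac{(1-f)\cdot 2 + f \cdot c}{2}, $$

so a single-copy loss at $f$ sits at $\log_2(1 - f/2)$ and a single-copy
gain at $\log_2(1 + f/2)$. A gain of one copy crosses the +0.1 call
threshold at roughly $f \approx 0.145$, a loss crosses -0.1 at
$f \approx 0.133$ — the model's intrinsic detection limit for the fixed
thresholds, independent of depth once depth noise is small.

`simulate_counts()` draws per-bin counts with expectation proportional to
$r$ times a smooth multiplicative GC bias, the bin's mappability, and its
length fraction, scaled so the expected total over usable bins equals
`total_pairs`. Counts are negative-binomial with variance
$\mu + d\,\mu^2$; $d = 0$ is the Poisson limit.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `bin_size` | 5,500,000 | bp | the published window width; large enough for shallow depth, small enough to resolve arm-level events |
| `step` | = `bin_size` | bp | non-overlapping tiling; overlap would double-count aberrations in the CNI sum |
| `amp_threshold` / `del_threshold` | +0.1 / -0.1 | log2 | the published call limits; strict inequalities, ties neutral |
| `positivity_min_bins` | 5 | bins | published positivity rule, inclusive |
| `min_mapq` | 60 | MAPQ | published filter: duplicates and MAPQ < 60 removed (strict) |
| `log2 floor` | 2^-8 | ratio | keeps zero-count bins finite; floored bins still count as deletions |
| `min_arm_fraction` | 0.6 | fraction | arm call requires 60% of the arm's usable bins aberrant in one direction; conservative, configurable |
| `deep_del_log2` | -1.0 | log2 | homozygous-deletion evidence; for pure cn 0 this needs tumor fraction > 0.5 |
| `focal_amp_log2`, `max_focal_bins` | 0.58, 3 | log2, bins | a focal amplification is a short (+1) run peaking above ratio 1.5 |
| `total_pairs` (simulator) | 2e6 | read pairs | see below |
| `dispersion` (simulator) | 1e-4 | — | mild overdispersion; shallow-WGS bin counts are canonically overdispersed Poisson |
| `gc_bias` (simulator) | ±20% over GC 0.3–0.6 | — | gentle unimodal curve, so correction is exercised but not dominant |

### Why 2e6 simulated pairs

Per-bin depth sets the log2-ratio noise: with $N$ pairs spread over $B$
usable bins, the Poisson standard deviation of a bin's log2 ratio is about
$1/(\ln 2\sqrt{N/B})$. The fixed ±0.1 thresholds and the 5-bin positivity
rule define an operating point: a copy-neutral sample must essentially never
put 5 bins past ±0.1. At 2×10⁶ pairs over ~525 usable autosomal bins the
per-bin sd is ≈ 0.024 (0.028 with default dispersion), the neutral per-bin
false-call rate is ~4×10⁻⁴, and a neutral sample is SCNA-negative in
essentially every run — the same *noise-to-threshold* regime as a real
sample at clinical depth, reached at a fraction of the simulated-count cost
(the simulator draws one number per bin, so its runtime does not depend on
depth at all). Substantially fewer pairs would push the neutral false-call
rate past the positivity rule and make the fixed thresholds meaningless.

## What the simulator does and does not emulate

Emulated: segment-level integer copy-number truth (whole-chromosome,
arm-level, and 1–2-bin focal events, including homozygous deletion and
high-level amplification); dilution of tumor signal by normal cfDNA; smooth
GC bias; mappability weighting; partial terminal bins; overdispersed
counting noise; per-sample seeding derived from a cohort master seed.

Not emulated: fragment-length (fragmentomics) structure, sequencing or
mapping errors, reference artifacts such as centromeric count spikes,
subclonal heterogeneity (one clone per sample), germline CNVs, and
FFPE-specific biases of tissue comparators. Passing simulation tests
therefore demonstrates the *arithmetic and statistical* correctness of the
pipeline at a realistic operating point — not clinical sensitivity on real
CSF, which depends on cfDNA yield and tumor shedding.

The built-in templates place focal events on bin-aligned segments
(`cdkn2ab_homdel` spans the two 9p21 bins containing the CDKN2A/B locus;
`focal_amp` one 12q bin). This makes expected values exact; a real focal
event overlapping a bin boundary is diluted by the bin's length-weighted
copy number, which `bin_mean_cn()` models directly.

## Numerical and design choices

* **Tie-breaks**: log2 exactly ±0.1 is neutral; exactly 5 aberrant bins is
  positive; MAPQ exactly 60 is retained. One consistent rule each.
* **Counting unit**: a read *pair*, assigned to the bin containing the
  leftmost mate's start. Each pair contributes once; pairs on chromosomes
  absent from the grid are dropped and tallied.
* **Correction order**: GC/mappability correction precedes median
  normalization; the corrected counts keep the raw scale (fit normalized to
  mean 1) so they remain interpretable as counts.
* **Concordance unit**: the bin, direction-aware. Bins aberrant in both
  profiles but in opposite directions are reported as `discordant_direction`
  rather than folded into "shared", because they agree only in being
  abnormal, not in what happened.
* **Arm assignment**: a bin belongs to the arm containing its midpoint;
  bins straddling the centromere gap belong to neither arm.
* **Flag thresholds at low tumor fraction**: the deep-deletion rule
  (log2 < -1.0) requires tumor fraction above ~0.5 for a pure homozygous
  deletion; template specificity for `cdkn2ab_homdel` and `focal_amp` is
  therefore exercised at f = 0.6 in the test suite, and arm-level templates
  at f = 0.4.
* **Degenerate inputs**: an all-zero count vector raises "insufficient
  coverage"; a constant-GC grid short-circuits the decile fit to a single
  global median; fewer than 30 usable bins demotes loess to `median_bins`;
  an empty mappability track yields mappability 0 and (under any positive
  filter) no usable bins.
* **Determinism**: all simulation randomness flows from integer seeds
  (`derive_seed()` keeps derived seeds below 2^31); the RNG state of the
  calling session is saved and restored around every draw.

## Problem sizes used in tests and reproduction

The shipped tests and the reproduction script run the full HG19 grid
(574 bins, 564 usable) with 2×10⁶ simulated pairs per sample; operating
characteristics (specificity of neutral samples, sensitivity of the +7/-10
template at f = 0.4, template-specific flag firing) use 100 seeded
replicates per condition, and mixture-recovery checks use 4 replicates at
dispersion 0. The default simulated cohort is 6 controls plus 6 tumors at
tumor fractions 0.1–0.7. Note that two of the six default tumors are
focal-only templates with at most 2–3 aberrant bins: by construction they
can never satisfy the >= 5-bin positivity rule, even though their diagnostic
flags fire — positivity and diagnostic yield are deliberately different
questions.

## Known limitations

* Bin boundaries are this package's own tiling; agreement with other
  implementations is at the level of metric definitions, not bin-for-bin.
* No absolute copy-number or ploidy estimation, no allele-specific analysis,
  no segmentation, no mutation calling — out of scope by design.
* The fraction score is a *proxy* for tumor-cfDNA content, not a calibrated
  estimate of f: for a single-copy loss at fraction f its expectation is
  |log2(1 - f/2)|, which is monotone in f but not linear, saturates for
  whole-genome doubling-like profiles, and mixes gains and losses.
* Arm calls on acrocentric short arms (13p, 14p, 15p, 21p, 22p) rest on very
  few usable bins and are neutral in practice.
* QC depth is an approximation (`filtered pairs × 2 × read length /
  genome size`), not a per-base pileup.
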