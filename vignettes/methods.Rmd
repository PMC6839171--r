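---
title: "Methods: two-tier enhancer prediction, condition dynamics and target linking"
author: "enhanceRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-tier enhancer prediction, condition dynamics and target linking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices, and the known limitations.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Signal model and preprocessing

All computation happens on fixed 100-bp bins (`GenomeBins`). Reads are
assigned to exactly one bin — the bin containing the 5'-most aligned
position (start on the forward strand, end on the reverse strand) — so total
counts are conserved and the rule is unambiguous at bin boundaries. Paired
data can be counted once per fragment via the first mate (`fragment = TRUE`
in `binCounts`).

Raw counts are input-normalized per bin as
`log2(treatment + 1) − log2(control + 1)`; the pseudo-count keeps empty bins
finite and the difference-of-logs form is algebraically identical to the
log-ratio of pseudo-counted counts. The H3K4me1/H3K4me3 ratio track is built
after shifting both input-normalized tracks to be non-negative by
subtracting their genome-wide minima; the minima are *stored in the trained
model* and re-applied verbatim at prediction time, so the ratio feature is
computed identically in training and prediction. Before prediction on a new
sample, each input-normalized mark track is quantile normalized to the
distribution of the corresponding training track (rank matching with
average-rank ties and linear interpolation against a stored reference of at
most 10,000 sorted quantiles). This is what makes a model transferable
across samples of different sequencing depth; the test suite demonstrates
the effect by binomially thinning a sample's reads to 30% and comparing
predictions with and without the normalization. Whether zero bins should be
excluded from the reference is an open question; we normalize all bins.

## The two-tier classifier

Two probability forests (`ranger`, M = 100 trees each, all other
hyperparameters at library defaults and recorded in the model provenance)
factor the enhancer probability:

* **Classifier 1** — active vs inactive chromatin — sees only H3K27ac:
  2N+1 = 11 features (the bin plus N = 5 bins per side, an 1100-bp window).
  Positives: enhancers and active promoters; negatives: inactive promoters,
  intragenic and intergenic background.
* **Classifier 2** — enhancer vs active promoter, given active — sees all
  three marks plus the ratio track: 44 features. Positives: enhancers;
  negatives: active promoters.

The per-bin enhancer probability is the product of the two, which holds
exactly (it is enforced by the `ProbabilityTrack` validity method). The
window size reflects the physical anatomy being detected: an accessible
center with marked nucleosomes on both flanks spans roughly a kilobase.

Training sets are stratified samples emulating genome composition:
1000 regions at 10% enhancers / 5% active promoters / 5% inactive
promoters / 10% intragenic / 70% intergenic for classifier 1, and
150 regions at 2:1 enhancer:active-promoter for classifier 2. Non-integer
quotas are resolved by largest remainder. Promoter labels follow the
expression rules: active = FPKM > 2 in *every* replicate *and* the TSS bin
overlaps an accessibility peak; inactive = FPKM 0 in every replicate. Genes
with any replicate in (0, 2] fall between the stated cutoffs and are
excluded from both classes — the conservative reading. Candidate enhancers
are re-centered on the midpoint of their best-overlapping accessibility
peak (ties to the leftmost peak) and dropped without overlap. Background
bins are drawn at least 1 kb away from any labeled element to avoid label
leakage; the margin is our choice, as no exclusion distance is standard.

Peak calling is greedy: bins with probability ≥ 0.5 are sorted by
descending probability (ties: lower coordinate), expanded by five bins per
side, and any window overlapping an accepted window is discarded. Windows
are clipped at chromosome ends — a summit within five bins of an end yields
a region narrower than 1100 bp. The emitted peak probability is the
summit-bin probability; no aggregation over the window is implied. Peaks
within 12.5 kb (edge to edge) can be merged into enhancer clusters.

## Condition dynamics

Per-sample enhancer probabilities form the matrix A (bins × samples). For a
condition pair, the statistic T = (μ₁ − μ₂ − w₀)/S_Δ tests
H₀: |μ₁ − μ₂| ≤ w₀, with S_Δ the pooled standard deviation scaled by
√(1/n₁ + 1/n₂). Defaults: w₀ = 0.5 (so a bin must move by more than half
the probability scale), P* = 0.05.

Numerical choices, all deliberate:

* **ε replacement.** With a single replicate in either group the pooled SD
  is undefined and is replaced by ε = 1e−8; consequently any bin with
  |μ₁ − μ₂| > w₀ becomes maximally significant in the one-replicate setting.
  We apply the same replacement when the pooled SD is exactly zero (e.g. a
  constant matrix), otherwise T would be 0/0 at w₀ = 0; a constant matrix
  then yields identical statistics and p-values of 1 everywhere.
* **Both directions.** The statistic is one-sided, so each unordered pair is
  tested in both orders; a `PairTest` carries forward and reverse p-values.
* **Null construction.** One global shuffle of the pair's submatrix entries,
  with the statistic recomputed per bin: n_null = number of bins, so the
  p-value floor is 1/(1 + bins) with add-one counting. A `rounds` argument
  multiplies the null size. Each pair uses a sub-seed derived from the user
  seed, so results are reproducible and pairs are not artificially coupled.
* **Five-bin window.** A bin is called differential in a direction only when
  its own p-value and those of two neighbors on each side are all ≤ P*; at
  chromosome ends, where neighbors do not exist, the condition simply fails
  (no wrap, no padding).
* **No FDR correction.** The raw empirical threshold P* is applied, matching
  the method's definition; users needing family-wise control should lower
  P* or raise `rounds`.

Patterned bins merge into regions within 2 kb (same pattern, same
chromosome), carrying the lowest-p bin as peak; overlapping regions of
different patterns merge and take the pattern of the lowest peak p-value.
For |C| conditions the pattern universe holds 3^C(|C|,2) − 1 informative
patterns — 26 for three conditions.

One subtlety: raising w₀ shifts the true statistics and the null together,
so the claim "higher w₀ selects a subset of bins" is not an algebraic
identity. It holds in practice because planted/real differential bins have
small pooled SD relative to null bins; the suite asserts it on a fixed
synthetic fixture.

## Target linking

Expression counts are variance stabilized — by default median-of-ratios size
factors followed by log2(x + 1), with `method = "vst"` delegating to DESeq2
when available. The default keeps all-zero genes at zero and is validated in
the suite by the slope of log(sd) against mean after transforming simulated
negative-binomial counts spanning three decades.

For every (differential region, gene) pair sharing at least one TAD, the
Pearson correlation between the region's per-sample summit probability and
the gene's normalized expression is computed across sample columns (at least
three samples; replicates are used as-is rather than averaged per
condition). Pairs with r ≥ 0.9 become regulatory units; negative
correlations are never emitted. Choices: the region's probability is its
summit-bin value (a mean-over-region option exists); gene membership in a
TAD is judged by the TSS; TADs may overlap and membership is tested per TAD.
The 0.9 default suits designs with strong on/off dynamics — 0.7 is more
appropriate when activity varies gradually, and is what the planted-recovery
test uses, since its expression noise acts on a compressed scale. Topology
labels are resolved region-first: a unit whose region links several genes is
1:many even if its gene is also linked by several regions; both flags are
retained.

A nearest-gene baseline (`nearestGeneBaseline`) pairs each region with the
closest TSS, for the standard comparison showing that proximity is not
regulation; the suite contains a planted decoy construction where the
baseline picks a 5-kb decoy while correlation linking recovers the true
15-kb target.

## The synthetic-data generator

The generator is the package's study design, not a tuning knob. It emulates:

* **Enhancer anatomy** — an accessible, signal-free center flanked by a
  phased nucleosome array: Gaussian read bumps (sd 100 bp) of H3K4me1 and
  H3K27ac at ±200, ±400 and ±600 bp with amplitudes 1 / 0.8 / 0.5 of the
  planted strength (8× a 2-reads/bin background), with slight positional
  jitter per element — real phasing is imperfect. The enrichment domain
  spans ~1.5 kb, as histone-mark domains around real elements do.
* **Promoters** — the same geometry with H3K4me3 + H3K27ac (and no H3K4me1),
  so classifier 2 has a genuine discrimination task; inactive promoters add
  nothing.
* **Background** — negative-binomial counts (dispersion 0.1) per bin, per
  sample; the input track is background-only.
* **Design** — the default benchmark genome is 2 × 1 Mb (20,000 bins),
  2 conditions × 2 replicates, 160 enhancers (30% active in all conditions,
  the rest specific to one condition round-robin), 60 active and 60 inactive
  promoters. The counts are sized so a labeled pool supports the default
  1000/150-region training compositions (~104 enhancers active per
  condition).
* **Expression** — each enhancer gets a target gene in its TAD (TSS 5-25 kb
  away); target means scale 8-fold with the enhancer's per-condition
  activity, decoy genes are condition-independent, counts are
  negative-binomial (dispersion 0.05).
* **Label curation noise** — `labelPoolFromTruth` jitters training enhancer
  centers by up to ±150 bp, emulating the imprecision of re-centering real
  training enhancers on accessibility peaks. Without it a forest trained on
  perfectly centered windows is unrealistically shift-intolerant.

It does *not* emulate: read-level artifacts (mappability, duplicates, GC),
fragment-length effects, copy-number or chromatin-domain heterogeneity,
enhancer-size diversity, promoter-proximal enhancers, or expression driven
by anything other than a single enhancer. Passing the planted-recovery tests
therefore demonstrates internal consistency of the pipeline under its own
assumptions — not field performance on real chromatin.

## Problem sizes and determinism

The test suite runs everything at desk scale: the benchmark pipeline uses
two independently seeded 2 × 1 Mb genomes (train on one sample of genome A,
evaluate all four samples of genome B); the peak-caller oracle comparison
uses 1000 random 10,000-bin tracks; the type-I check uses a 10,000-bin null
matrix. These sizes were chosen so the full suite completes in about a
minute while keeping Monte-Carlo margins tight. Every stochastic step —
simulation, training-set sampling, forest fitting (single-threaded ranger
with a fixed seed), permutation shuffles — is reproducible from explicit
seeds, and seeded helpers restore the caller's RNG state.

In the type-I test, all bins are compared against a single estimated null
quantile, so the exceedance fraction carries binomial noise plus an equal
contribution from the shared threshold estimate; the acceptance margin uses
Var ≈ 2·α(1−α)/n accordingly.

## Known limitations

* The permutation null treats bins as exchangeable; strong genome-wide
  covariance (e.g. copy-number) would miscalibrate it.
* With one replicate per condition, the ε rule makes significance a pure
  threshold on |μ₁ − μ₂| − w₀; this is documented behavior, not an error.
* Pearson correlation across few samples (the minimum is 3) is noisy;
  regulatory units from small designs should be treated as candidates.
* The model serializes with its quantile references and shifts, and a
  versioned archive refuses to load across incompatible formats; forests are
  not portable across ranger major versions.
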