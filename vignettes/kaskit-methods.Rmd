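---
title: "Models and methods behind kaskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kaskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaskit)
```

## What KAS-seq measures and what this package does with it

KAS-seq labels guanines in single-stranded DNA with N3-kethoxal, so read
density reports the transcription bubbles of engaged RNA polymerases rather
than the polymerase protein or its RNA product. Its strand-specific variant
(spKAS-seq) preserves which DNA strand each read came from, which makes
strand-asymmetric ssDNA exposure — the signature of an R-loop — detectable.

kaskit takes deduplicated mapped fragments (BED tags) and externally called
candidate peaks as inputs and implements the downstream analyses: quality
control, sharp/broad peak integration, per-gene transcription-cycle
indices, single-stranded transcribing (SST) enhancer classification,
strand-imbalance R-loop calling with RNase H filtering, and time-course
trajectory classification. Trimming, alignment, deduplication, and the
MACS2/epic2 peak callers themselves are out of scope: their outputs are
this package's inputs.

All coordinates are 0-based half-open (the BED convention) everywhere —
internally, in every file read, and in every file written. Chromosome
names match by exact string equality; no "chr" aliasing is attempted,
because silent aliasing hides genome/annotation mismatches.

## Coverage and densities

Density uses read-count semantics: a tag contributes once to every bin or
region it overlaps by at least one base pair. For a region of width $w$ bp
containing $c$ overlapping tags out of a library of $N$,

$$\mathrm{RPKM} = \frac{c \cdot 10^9}{w \cdot N}.$$

Single-end tags shorter than 150 bp are extended to 150 bp from their 5'
end in the direction of their strand (`extend_reads()`); longer tags are
left alone — extension compensates for short reads, it is not a resizing.
The library size for RPKM is the tag count after deduplication and
extension, computed once per sample so that every ratio in the package
shares one normalization constant.

Wherever a density appears in a denominator, a zero is floored at
$\delta$, the RPKM a single fragment would have in that region for the
relevant library. This guard is scale-aware and deterministic, avoiding an
arbitrary epsilon.

## Quality control

* **FRiP**: fraction of tags overlapping the merged peak set.
* **Library complexity** (on pre-deduplication tags, grouped by 5'
  position): NRF = distinct/total, PBC1 = single-hit/distinct, PBC2 =
  single-hit/double-hit positions. When no position is seen exactly twice
  PBC2 is reported as infinite with a flag rather than failing: small
  perfectly complex libraries are legitimate.
* **Fingerprint**: bin counts (500 bp genome-wide bins by default — the
  common fingerprint convention; the bin size is a parameter) sorted
  ascending and accumulated to a curve from (0,0) to (1,1). Concentrated
  signal hugs the x-axis; uniform background lies on the diagonal.
* **Saturation**: seeded subsampling without replacement at fractions
  0.1–1.0, FRiP recomputed against the fixed full-data peak set.
* **Replicate correlation**: Pearson r on log2(RPKM + 1) region densities.
  The transform and region set behind the published correlation panels are
  not specified in detail anywhere we could find; this choice is ours and
  is documented rather than inferred.
* **Verdict**: `pass` requires at least 50,000 combined sharp + broad
  peaks *and* FRiP strictly above 40%. These thresholds were recommended
  for live human/mouse cell lines; both are arguments, not constants,
  because they are not expected to transfer to frozen tissue or small
  genomes. A failing sample gets `warn`, never an error.

## Peak integration

Sharp candidates (MACS2-style, already screened upstream at q ≤ 0.01 and
1.5× vs Input) are re-screened: a candidate is kept iff its case density
is ≥ 5× the Input density *and* ≥ 2× the mean case density of its usable
shores. Shores are equal-width flanks (the same rule used for enhancer
shores, adopted here because no separate width is defined for peak
shores); a shore clipped below half its nominal width at a chromosome edge
is unusable, and a candidate with no usable shore is dropped rather than
scored against a degenerate background. Broad peaks are derived by
subtracting accepted sharp peaks from epic2-style broad candidates;
leftover fragments shorter than 150 bp (one read length) are discarded as
not meaningful "broad" signal. Sharp and derived-broad peaks are
base-wise disjoint by construction.

Feature annotation assigns each peak by its midpoint with priority
promoter (TSS ± 2 kb) > terminator (TES to TES + 3 kb) > gene body >
intergenic, which yields a partition whose percentages sum to 100. Note
the two promoter definitions in the package: ±2 kb for annotation, ±0.5 kb
for the transcription indices below; both are exposed as distinct
arguments because the analyses they serve use different windows.

## Transcription-cycle indices

For each gene, with densities computed independently per region:

* promoter proximal: TSS ± 500 bp
* gene body: TSS + 500 bp (strand-ward) to TES
* termination region: TES to TES + 3 kb (strand-ward)

$$\mathrm{PI} = \frac{\mathrm{ssDNA}(\mathrm{promoter})}{\mathrm{ssDNA}(\mathrm{body})},\quad
\mathrm{EI} = \frac{\mathrm{ssDNA}(\mathrm{promoter}) + \mathrm{ssDNA}(\mathrm{body})}{2},\quad
\mathrm{TI} = \frac{\mathrm{ssDNA}(\mathrm{termination})}{\mathrm{ssDNA}(\mathrm{body})}.$$

Genes narrower than 1 kb are excluded (the promoter window would swallow
the body) and reported with a reason code instead of being silently
dropped; overlapping genes are scored independently because the index
definitions carry no exclusion rule. PI and TI are undefined (null) when
the body density is zero; EI remains defined. Tertile grouping
(high/medium/low) splits the non-null values at the empirical 1/3 and 2/3
quantiles with stable gene-name tie-breaking; an all-tied vector goes
entirely to `medium` with a warning.

## SST enhancers

An active enhancer (supplied externally, e.g. distal H3K27ac peaks) is
*single-stranded transcribing* when its ssDNA density is significantly
higher than that of its shores — flanking regions of width equal to the
element. Elongation pass-through produces ssDNA across element and shores
alike and must not qualify; promoter-proximal pausing concentrates ssDNA
on the element.

The decision rule is a conjunction: fold enrichment (enhancer mean over
pooled shore mean) ≥ 1.5 *and* one-way ANOVA p ≤ 0.05 across three groups
— per-50 bp-bin RPKM values in the enhancer, left shore, and right shore.
The ANOVA's unit of replication is not stated in the method this package
implements; bins are the only within-sample replicate available without
biological replicates, so bins are what we use, and p-values are used raw
(not multiplicity-adjusted) as published. Bin observations are RPKM, not
raw counts, so clipped shores remain width-comparable. Enhancers narrower
than two bins or with an unusable shore are labeled `unusable`. The F
statistic is computed from the classical sums of squares with explicit
conventions for the degenerate cases (all observations identical: F = 0,
p = 1; perfect separation: F = ∞, p = 0).

## R-loop detection

spKAS-seq tags are strand-split; 500 bp windows are tiled over the
supplied spKAS peaks. The tiling step defaults to 500 bp (non-overlapping)
— the published description says "sliding" without a step, and
non-overlapping windows keep the independence assumptions of
Benjamini–Hochberg clean; the step is an argument for users who want
overlap.

With two or more replicates per strand the test is a negative-binomial
Wald test authored in this package:

1. median-of-ratios size factors (per-window geometric mean across
   samples, zero-containing windows excluded; each factor is the median
   ratio);
2. per-window dispersion by method of moments, pooled across the two
   strand conditions, then shrunk 50/50 in log space toward a fitted
   mean–dispersion trend $\alpha(\mu) = a_1/\mu + a_0$ (floored at
   $10^{-8}$). The trend is fit by least squares on the raw — possibly
   negative — moment estimates, which keeps the intercept unbiased;
   windows whose moment estimate is non-positive take the trend value
   directly, since log-space shrinkage is undefined there;
3. Wald statistic = log2 fold change (half-integer pseudo-count) over its
   delta-method standard error under NB variance $\mu + \alpha\mu^2$,
   two-sided normal p, BH adjustment across windows.

With a single replicate the NB dispersion is unidentifiable, and the test
falls back to a two-sided exact binomial test of the pooled plus count
against the library-size-adjusted expected plus fraction.

Significant windows (adjusted p ≤ 0.05) are partitioned by dominant strand
and merged (gap 0 by default — "merged" with no stated gap) into R-loop
regions. The R-loop density track is the per-50 bp-bin absolute difference
of plus and minus RPKM.

RNase H degrades the RNA of RNA–DNA hybrids, so signal loss under RNase H
treatment is the gold-standard confirmation. The published threshold is a
fold change of 1.5 with an ambiguous direction; we read it as *sensitivity
means signal loss*: a region is RNase H-sensitive iff
WT density / treated density ≥ 1.5 (treated denominator floored at
$\delta$). The replicate design of the underlying two-condition comparison
is likewise unstated; we use an unpaired design.

## Time-course trajectory classification

Counts per feature per sample (features × ordered timepoints × replicates)
are fit with three nested NB mean models at fixed per-feature dispersion:

* constant: $f(t) = h$ (1 parameter)
* sigmoid: $f(t) = h_0 + (h_1 - h_0)\,\sigma(\beta(t - t_1))$ (4)
* impulse: $f(t) = \frac{1}{h_1}\,[h_0 + (h_1 - h_0)\,\sigma(\beta(t - t_1))]\cdot[h_2 + (h_1 - h_2)\,\sigma(-\beta(t - t_2))]$ (6)

with $\sigma$ the standard logistic. The published pipeline delegates this
step to ImpulseDE2; reproducing that package's every internal heuristic is
out of scope, so kaskit implements the scientific contract — NB noise,
impulse dynamics, steady-vs-transient split — as a from-scratch
likelihood-ratio framework whose behaviour is verified by simulation
rather than by matching another implementation's internals. The design is
case-only (no control series), matching the UVB time-course design this
analysis was built for.

Dispersions come from the same moment/trend-shrinkage machinery as the
R-loop module, estimated across replicates within timepoints and shrunk
across features. Size factors are rescaled to geometric mean 1 before
fitting: the NB dispersion is defined on the raw count scale, and this
makes the classification exactly invariant to a global rescaling of the
size factors.

Impulse likelihoods are multi-modal, so optimization is bounded L-BFGS-B
($\beta \in [0.05, 20]$, levels ≥ $10^{-6}$, log-scale for positive
parameters, $t_2 = t_1 + e^{\text{free}}$ to enforce ordering) with
multi-start: transition times initialized on the observed timepoint grid,
plus degenerate starts seeding each richer model with the simpler model's
solution, which guarantees the nested log-likelihood ordering up to
optimizer tolerance.

Classification: LRT impulse vs constant (5 df) gives `p_diff`; impulse vs
sigmoid (2 df) gives `p_trans`; each family is BH-adjusted. Transient
requires both ≤ α; steady requires only the first. Direction compares the
fitted level at the internal extremum (transient) or the last timepoint
(steady) with the fitted level at the first timepoint — the published
up/down counts never define their reference point, so this one is ours.

## The synthetic-data generators

Every analysis above is exercised end to end on seeded synthetic data
(`sim_spec()` and the `simulate_*()` functions). The defaults describe a
small but realistic study:

* two 2 Mb chromosomes; 100 non-overlapping genes of 5–20 kb on both
  strands, inter-gene gaps above 6.5 kb so that the termination regions of
  convergent gene pairs never overlap (the per-gene region-rate model
  assumes disjoint regions);
* KAS tag rates 10 / 2 / 4 tags per kb in promoter / body / termination
  over a 0.1 per kb background (so true PI = 5, TI = 2), placed as Poisson
  counts of 36 bp raw tags that the pipeline itself extends to 150 bp —
  synthetic data exercise the real code path, not a parallel one.
  Optionally, per-gene log-normal multipliers on the promoter and
  termination rates emulate gene-to-gene variation in pausing and
  termination efficiency (off by default; used when replicate concordance
  of a heterogeneous cohort is the property under study);
* 1 kb enhancers at 80 tags per kb (4 per 50 bp bin), half "paused" with
  shores at a quarter of that rate, half "pass-through" with shores at the
  full rate;
* spKAS windows at NB mean 50 and dispersion 0.05 with 2 replicates per
  strand; planted imbalanced regions are consecutive-window blocks at
  plus:minus mean ratio $2^{\pm \mathrm{lfc}/2}$, and the RNase H-treated
  condition divides exactly the planted windows' counts by 4. Tags are
  materialized 150 bp long and fully inside their window, so window
  re-counting reproduces the simulated count matrix exactly;
* time-course features in three classes (constant, monotone sigmoid,
  impulse pulse) at 6 timepoints (0–12 h, the UVB design) × 2 replicates,
  NB dispersion 0.05, baselines 30–120, fold changes 3–8 (monotone) and
  4–10 (pulse) in both directions.

What the generators deliberately do *not* emulate: sequence content (no
FASTA; kethoxal chemistry and guanine specificity are below this
abstraction level), GC bias (none was observed in the assay this package
supports), mappability structure, or copy-number variation. Passing tests
therefore demonstrate the statistical machinery under the stated model,
not robustness to those artifacts in real libraries.

## Problem sizes and numerical conventions

The test suite and the acceptance script run, per invocation: 500 random
interval-algebra instances against a per-base oracle; index recovery at
1e5 tags over 100 genes; a 100-enhancer SST cohort; 5,000 null plus 5,500
spiked strand-imbalance windows; a 2,000-window RNase H experiment with
100 planted regions; and 600 + 200 time-course features. These sizes give
every binomial proportion checked a standard error below ~1.5 percentage
points while keeping a full run in single-digit minutes on one CPU.

Ties in tertile grouping break by gene-name order (stable across runs);
BH adjustment delegates to `stats::p.adjust` and is tested against the
step-up definition; the exact binomial test delegates to
`stats::binom.test` and is tested against exhaustive enumeration; the
one-way ANOVA is computed from closed-form sums of squares and tested
against `stats::oneway.test`. Degenerate inputs (empty peak sets, all-zero
tracks, zero-variance vectors, short genes, clipped shores) either return
a defined convention or fail with a named reason — never silently.

## Known limitations

* The NB Wald test is mildly anticonservative at two replicates (null
  type-I fraction ≈ 0.06 at nominal 0.05 in calibration runs); with more
  replicates the moment dispersions stabilize and calibration tightens.
* Non-canonical structures such as H-DNA can also expose ssDNA
  asymmetrically; only the RNase H comparison separates them from true
  R-loops, which is why the sensitivity filter is part of the module.
* RPKM absorbs library size but not global signal shifts; a spike-in
  normalization path is not implemented.
* `h_0` (the pre-transition plateau of the impulse model) is weakly
  identified when only one timepoint precedes the rise; fitted curve
  levels are identifiable and are what the tests assert.
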