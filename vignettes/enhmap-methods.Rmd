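---
title: "enhmap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{enhmap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how each stage of `enhmap` is defined, which
choices were genuinely open, and what the synthetic data do and do not
establish about real data.

## Coordinates and interval algebra

All coordinates are 0-based half-open (`[start, end)`, BED-native)
throughout the package. Region boundaries quoted as browser positions
(1-based inclusive), such as the extended MHC at chr6:29,580,000–
33,100,000, are converted on construction by subtracting 1 from the
start only. Merging and overlap queries are delegated to
IRanges/GenomicRanges after the convention shift; the test suite pins
the behaviour to independent per-base boolean-array and quadratic
all-pairs oracles on random inputs, so the convention shift itself is
under test.

The default co-incidence threshold everywhere is 1 bp. No published
minimum overlap exists for these comparisons; 1 bp is the weakest
defensible reading and every classifier exposes `min_overlap` so the
choice can be tightened. CE fractions are monotonically non-increasing
in this knob (tested).

## Binding intervals

A binding interval is derived per (condition, factor): the base-pair
**intersection** of the two individuals' peak sets, with contiguous or
overlapping shared regions merged (gap 0). Intersection rather than
union is the conservative definition of a replicate-consensus footprint
— a base belongs to a BI only if both individuals show enrichment over
it. Groups with any number of individuals other than two are a
configuration error rather than a silent degradation, because the
consensus definition is pairwise.

The representative summit of a BI is the summit of its highest-scoring
member peak, ties broken by leftmost coordinate — a deterministic rule
so that segment extraction is reproducible.

The DCS is defined as the **count** of distinct feature tracks (DHS,
RFX5, CREB1, ATF1, NFYA, NFYB by convention; any named track list is
accepted) overlapping the BI by ≥ 1 bp, giving an integer in 0–6 for the
canonical six-track panel. A weighted variant would need per-track
calibration data that a desk-scale reimplementation does not have; the
count is transparent and sufficient for thresholds such as "DCS > 4".

## Gene association

Distance is measured from the TSS to the nearest BI **edge** (0 when
the TSS is inside the BI), signed by gene-strand orientation (negative
= BI upstream of the TSS). Edges rather than summits or midpoints are
used because the BI, not a point estimate within it, is the unit of
association. The association radius `< 10 kb` is strict, the proximal
cutoff `≤ 2 kb` inclusive — the literal readings of "less than 10 kb"
and "within 2 kb". Many-to-many links are preserved: one gene may carry
several BIs and one BI may serve several genes.

## PWM scoring and the tri-motif module

Count matrices are column-normalised, a pseudocount of 0.01 is added to
every frequency cell and columns renormalised (avoiding `ln 0` with
negligible distortion), and the per-position information is
`I(i) = Σ_b f(i,b) ln(4 f(i,b))` (nats; 0 for a uniform column, `ln 4`
in the pure-base limit). A window scores

```
score = (Current − Min) / (Max − Min),  Current = Σ_i I(i) · f(i, b_i)
```

with Min/Max the per-position worst/best attainable contributions — the
MATCH matrix-similarity score, min–max normalised to [0, 1] so that an
"average rate" across motifs is well defined. `N` bases contribute the
per-position minimum, so an ambiguous window can never outscore its
worst resolved substitution (tested as an invariant). The core-region
filter of the original MATCH tool is deliberately omitted: no cutoffs
are published for this analysis, and the filter only prunes candidates
rather than changing the score.

The module search maximises the mean of the three component scores over
all placements with strictly increasing, non-overlapping starts on a
single orientation of the 150 bp segment; both orientations are tried
and ties resolve to the leftmost RFX5 start, then CREB, then NF-Y, then
the forward orientation. Two open questions were decided here: motifs
must share one orientation (the SXY module is a single-strand cis
arrangement), and placements may not overlap (the natural reading of
"in the correct order"). The search is an exact dynamic programme over
suffix maxima, O(segment × 3) per orientation, and is verified against
exhaustive enumeration of all ordered placements on small instances.

Control segments follow the published construction: for each of 1,000
randomly selected genes (configurable; the synthetic pipeline scales
this down to 50), one 150 bp segment uniformly placed in the
strand-oriented window from 10 kb 5' to 150 bp 3' of the TSS.

## eCDF enrichment

Genes are ranked by DE p-value with average ranks on ties; a gene's
rank-quantile is `u = rank/N`. The target set's eCDF is evaluated on a
101-point grid with a **pointwise bootstrap percentile band**
(resampling the target set with replacement, default 1,000 resamples,
level 95%). The published figure states a 95% confidence interval
without a construction; a pointwise percentile band is the simplest
choice consistent with a per-curve interval, and its null calibration
is itself an acceptance check (coverage of the diagonal at the median
grid point within [92%, 98%] over 1,000 uniform-null replicates —
`band_null_coverage()` computes this; it comes out near 95%).

The deviation statistic `D = sup_u (F̂(u) − u)` (one-sided, above the
diagonal, attained at sample points) makes the visual "curve lies above
the diagonal" testable; its null is Monte-Carlo, from target-set-sized
uniform samples (default 10,000 reps, `(k+1)/(n+1)` estimator). The
finite ranking (u on a grid of 1/N) is approximated by continuous
uniforms; at N = 10,000 versus m = 200 the discrepancy is far below the
Monte-Carlo resolution.

## Allele-specific binding

Reads covering the SNP are filtered at mapping quality ≥ 20 and base
quality ≥ 20 (matching the study's read-filter spirit at the site
level), duplicates excluded; bases matching neither allele are reported
separately. Per individual, an exact binomial test against 0.5 is
reported; the **headline** cross-individual p-value is a two-sided
one-sample t-test of the allele-A fractions against 0.5. The published
test behind "66.1% (SD 8.1), P = 0.008" at n = 5 is not named; a
one-sample t-test on those summary numbers gives p ≈ 0.011, the same
order as the printed value, so the t-test is the default headline while
both layers are returned and neither is treated as the unique
reproduction. Degenerate inputs (all fractions
identical and ≠ 0.5, SD = 0) report the machine floor with a warning
rather than NaN.

## eQTL integration

A single-marker OLS of expression on dosage plus optional covariates
(e.g. leading expression principal components), two-sided slope t-test,
cis iff the gene TSS is within 1 Mb of the SNP. No FDR machinery is
included — the genome-wide scan belongs to the source cohort analysis;
this module exists to integrate one SNP's trans associations (default
threshold p < 3 × 10⁻⁴) with the BI-associated gene set.

## What the synthetic data emulate

`simulate_study()` produces, from one master seed: a uniform-base toy
genome (2 × 500 kb, 180 genes at ≥ 5 kb spacing — the densest layout
that still leaves 10 kb promoter windows inside the contigs), planted
consensus tri-motif modules centred in 25 promoter windows, 45 + 30
true CIITA BIs across two conditions with a shared core and a 60%
exactly-co-incident RFX5 (CE) fraction, per-individual peaks with
clamped Gaussian endpoint jitter (SD 20 bp), false negatives, and
individual-specific false positives (0.5 per 100 kb), DE p-values with
the CE gene set drawn from Beta(0.2, 1) against a uniform background,
allelic counts at a planted 66.1% ratio (depth 100, five individuals),
and Hardy–Weinberg dosages (n = 281, MAF 0.3) with a cis effect of 0.5
and a 12-gene mediated trans network (8 genes binding-supported).

Deliberate simplifications: false positives are confined to alternating
1 kb parity bins per individual so they can never form a replicate
consensus (this makes "spurious peaks yield no BIs" a construction
property, not a probabilistic one); truth BIs keep ≥ 1.2 kb spacing so
clamped jitter cannot merge neighbours; RFX5 CE partners coincide
exactly with their CIITA BIs. The trans effect default (β_trans = 2)
was chosen because mediation caps the trans association strength at the
cis association's own t-statistic; even so, at residual SD 1 the
network sits near the p < 3 × 10⁻⁴ detection edge, which is itself a
realistic feature of trans mapping at n = 281.

What passing tests therefore show: the operations are exact relative to
their definitions (oracle equivalence), calibrated under the null (band
coverage, uniform p-values under permutation), and powered against the
planted effect sizes. What they do not show: robustness to fragment-
level read noise, mappability or GC structure, reference bias in allele
counting, correlated replicate error, or LD structure — none of which
the generator attempts to model, since alignment and peak calling are
consumed upstream.

## Numerical and degenerate-input conventions

- narrowPeak summit sentinel −1 → interval midpoint (deterministic).
- Zero-information (uniform) matrices score 0 for every window.
- Fully tied Mann–Whitney groups report p = 1 (the tie-corrected normal
  approximation is 0/0; there is no evidence against equality).
- Monte-Carlo p-values use the `(k+1)/(n+1)` estimator, so p = 0 is
  never reported.
- All generators are pure functions of (parameters, seed); pipeline
  stages that sample (control segments, bootstrap, Monte-Carlo) take
  explicit seeds.

## Problem sizes used in the test suite

Oracle comparisons run on ≥ 100 random instances per operation at
small sizes (≤ 40 intervals, 40 bp segments with 4 bp toy motifs);
calibration uses 1,000 null replicates (N = 10,000 genes, 200 targets,
1,000 bootstrap resamples); power checks use 100 replicates (module
contrast and DE enrichment), 500 (allelic ratio), and 100 (cis slope,
n = 281). These sizes were chosen so the full suite exercises every
claim in minutes on one core while keeping each check's resolution well
inside its acceptance margin.
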