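# enhmap

Tools for mapping transcription-factor co-occupancy around the CIITA
enhanceosome and integrating it with expression genetics. CIITA is the
master coactivator of MHC class II genes: it carries no DNA-binding
domain of its own and is recruited through an enhanceosome assembled on
the SXY promoter module by RFX (RFX5/RFXAP/RFXANK), CREB/ATF1 and NF-Y.
`enhmap` implements the downstream analysis a ChIP-seq study of this
system needs once peaks have been called:

- **Binding intervals (BIs).** Within one cell type/condition, a BI is
  the merged base-pair intersection of enriched peaks present in *both*
  individuals for a factor — a replicate-consensus footprint rather than
  a single-sample peak.
- **CE-marks and DCS.** A CIITA BI co-incident (≥ 1 bp by default) with
  an RFX5 BI is a CIITA-enhanceosome mark; the data coincidence score of
  a BI counts how many accessory tracks (DHS, RFX5, CREB1, ATF1, NFYA,
  NFYB) overlap it.
- **Gene association.** A BI is tied to a gene when the distance from
  the TSS to the nearest BI edge is `< 10 kb` either side (`0` when the
  TSS lies inside the BI); `|d| ≤ 2 kb` is proximal.
- **Tri-motif module scoring.** 150 bp segments centred on BI summits
  are scanned for RFX5 → CREB → NF-Y placements in order, on one
  orientation, non-overlapping. Each motif is scored with the MATCH
  matrix-similarity score

      score = (Current − Min) / (Max − Min),
      Current = Σ_i I(i) · f(i, b_i),   I(i) = Σ_b f(i,b) ln(4 f(i,b)),

  and the module score is the mean of the three components; groups of
  segments are compared with two-sided Mann–Whitney tests against a
  1,000-gene random promoter control set.
- **eCDF enrichment.** Genes are ranked by differential-expression
  p-value; the empirical CDF of a target set's rank-quantiles is drawn
  with a pointwise 95% bootstrap band against the no-enrichment
  diagonal, summarised by `D = sup_u (F(u) − u)` with a Monte-Carlo p.
- **Allele-specific binding.** Quality-filtered reads over a
  heterozygous SNP are tallied per allele; the cross-individual test is
  a one-sample t-test of the allele-A fractions against 0.5.
- **eQTL integration.** Single-marker OLS of expression on dosage (plus
  covariates), a 1 Mb cis/trans rule, and flagging of trans genes by
  binding support.

A synthetic-data module (`simulate_study()`) generates a toy genome with
planted BIs, promoter modules, DE enrichment, allelic ratios and a
mediated trans network — with full ground truth — so the entire pipeline
is testable end to end.

## Worked example

```r
library(enhmap)
sim <- simulate_study(seed = 7)          # 2 x 500 kb genome, 180 genes
run <- run_pipeline(sim, seed = 7)
print(run)
```

```
enhmap pipeline run
  BIs: 128 (75 CIITA, 45 CE-marks, CE fraction 0.60)
  gene associations: 326 (135 genes, 100% of CIITA BIs)
  module scan: target median 1.000 vs control 0.608 (p = 2.55e-10)
  DE enrichment: D = 0.267 (p = 0.0005)
  ASB: 65.2% (SD 5.8), p = 0.00436
  cis-eQTL: beta = 0.347 (p = 0.000236); trans supported 5 / 6
```

Reading the output: 128 consensus BIs were recovered from the noisy
per-individual peaks (75 CIITA across the two conditions, 60% of them
RFX5-co-incident, matching the planted CE fraction); segments around
known-target BI summits carry near-perfect planted modules (median
score 1.0) while random promoter controls sit near 0.6; the planted
DE-enriched CE gene set lifts the eCDF clearly above the diagonal; the
planted 66.1% allelic ratio and the cis effect are recovered within
their sampling noise. With the default residual noise the
mediated trans associations sit near the edge of detectability at the
stringent 3e-4 threshold, so only part of the planted 12-gene network
passes here (5 of the 8 binding-supported genes, 1 of the 4 others);
lowering `eqtl_noise_sd` recovers the full network (see the vignette).

`write_summary_json(run, "summary.json")` serialises the flat summary.

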