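---
title: "Dual-platform data fusion for food-origin authentication: methods and design"
author: "fuseMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-platform data fusion for food-origin authentication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuseMS)
```

## The problem and the approach

Verifying where a food product comes from, and how it was produced, is a
classification problem over analytical fingerprints. No single platform sees
enough: an ambient lipid fingerprint (rapid evaporative ionisation MS,
"REIMS") reflects diet and metabolism, while an ICP-MS element profile
reflects the water and environment the animal grew in. `fuseMS` implements
the mid-level data-fusion strategy that joins the two: each block is
compressed to its leading principal components, the per-block scores are
concatenated, and a discriminant model (PLS-DA or OPLS-DA by default) is
trained on the fused features. The reference application is salmon from five
origin/production groups — Alaska wild, Iceland farmed, Iceland wild, Norway
farmed and Scotland farmed.

The package covers the whole chain:

1. **Spectral preprocessing** — background subtraction, a relative
   total-ion-count (TIC) noise threshold of 1e-5, single-point multiplicative
   lockmass recalibration to leucine enkephalin ([M−H]⁻ 554.2615 Da),
   binning at 0.2 Da over m/z 100–1200 (5500 bins), and TIC row
   normalisation.
2. **Element-panel preprocessing** — internal-standard ratioing (e.g. Rh),
   certified-reference-material recovery/RSD QC, and filtering of elements
   that are predominantly below the limit of detection or on a
   configuration-supplied exclusion list.
3. **Fusion** — low-level (min–max-scaled concatenation) and mid-level (PCA
   compression at a cumulative-variance threshold, default 85%), both
   storing every fitted transform so held-out samples are projected, never
   re-fitted.
4. **Chemometrics** — NIPALS PCA with cross-validated Q², PLS-DA, OPLS-DA
   with an orthogonal signal correction filter, S-plot and VIP marker
   selection, LDA/PCA-LDA, k-NN, and a generic adapter that plugs external
   random-forest and SVM implementations into the comparison.
5. **Evaluation** — stratified k-fold CV with per-fold transform re-fitting,
   Hotelling T²/distance-to-model outlier screening, replicated test-sample
   majority calls, Kruskal–Wallis and pairwise Mann–Whitney element
   statistics, and an approximate CV-ANOVA with a permutation alternative.
6. **Synthetic data** — a two-block generator that emulates the five-group
   study design, so the whole pipeline is testable without any instrument
   data.

## Models and conventions

### Mass calculation and the marker panel

Deprotonated-ion masses are computed as the neutral monoisotopic mass minus
one hydrogen-atom mass (1.0078250319 Da), with no electron-mass term; this
convention reproduces 14 of the 18 published marker masses to ≤ 5×10⁻⁴ Da.
The four remaining records disagree with any standard convention by more
than that and are shipped verbatim with a `discrepant` flag: the printed
mass stays authoritative for bin annotation, the computed one for
validation. Three records additionally carry a printed bin label that is not
the 0.2-Da bin containing their printed mass (`bin_discrepant`); annotation
follows the mass, because the bin arithmetic is exact.

Bins are half-open intervals `[edge, edge + width)` with the left edge at
m/z 100 and labels at bin centres rounded to 0.1 Da — so an ion at 327.2324
lands in bin 1137 with label 327.3, matching the published "ion bin
category" convention.

### Latent-variable models

PCA and PLS2 use NIPALS with deterministic initialisation (the residual
column of maximal variance), tolerance 1e-10 and at most 500 iterations;
non-convergence (typical only for near-degenerate noise eigenvalues) raises
a warning and keeps the component as-is. Per-component explained variance is
‖t pᵀ‖²/‖X‖²; Q² is computed by row-wise fold exclusion (7-fold by default,
the usual software convention; 5-fold when parity with classifier CV is
wanted), with Q²(cum) = 1 − Π(PRESS/SS) for PCA and 1 − PRESS/SS(Y) for the
PLS family.

OPLS-DA follows the orthogonal-signal-correction scheme: the Y-predictive
weight basis is the span of XᵀY (for a binary contrast, the normalised Xᵀy
itself); each orthogonal component removes the part of the current X-loading
orthogonal to that basis. Because XᵀY is invariant under that deflation, the
training decomposition X = TPᵀ + T\_oP\_oᵀ + E is exact and every orthogonal
score is exactly uncorrelated with every Y column — both identities are
asserted to 1e-8 in the tests. Multi-class responses use multi-column-Y OPLS
with argmax prediction; S-plots are built one-vs-rest per class, as in the
published marker-selection workflow.

PLS-DA prediction is the argmax over predicted one-hot columns (ties go to
the lowest class index with a warning). VIP uses the standard weighted form
whose squared scores average exactly 1.

### Fusion choices

Before compression the spectral block is mean-centred and Pareto-scaled (the
usual choice for MS fingerprints); the element block is mean-centred and
unit-variance scaled, the chemometrics default for panels with heterogeneous
units. Retained components are the smallest number whose cumulative
explained variance reaches the threshold ("≥", ties toward fewer), capped at
min(n − 1, p, 250); the 250 cap accommodates the published 226-component
spectral regime. Concatenated scores are not re-weighted by default; an
optional per-block variance weighting is available but ships off, since the
reference workflow states none. Compression uses an exact economy SVD; the
NIPALS route exists separately and is oracle-tested against the same
decomposition, but iterating hundreds of components on a 5500-bin block is
needlessly slow.

### Outlier screening

A sample is screened against a fitted latent model by Hotelling T² over the
model scores (F-based limit) and by its residual distance to the model plane
(empirical training quantile). The two limits are each taken at 1 − α/2 — a
Bonferroni split — so the family-wise training flag rate calibrates to α;
with both tests at 1 − α the union would flag nearly 2α of clean data. In
cross-validation and test-set evaluation, flagged predictions are tabulated
in a separate Outlier column and counted as incorrect for the overall rate
(conservative; both numbers are reported).

### Univariate element statistics

Kruskal–Wallis (tie-corrected, chi-square tail) and pairwise two-sided
Mann–Whitney tests with Holm correction are delegated to the standard
`stats` implementations behind the package's interface; the suite checks
them against exhaustive permutation enumeration on small groups. CV-ANOVA is
implemented as a documented F-approximation on cross-validated PRESS versus
total Y variation — the proprietary original is not public — and a
label-permutation test is returned alongside as the recommended significance
measure (resolution 1/(nPerm + 1)).

## The synthetic generator: what it emulates, and what it does not

The generator reproduces the *statistical design* of the reference study:
five balanced groups, a 5500-bin spectral axis, a 20-element panel, and a
17-sample held-out set with 6 replicates each.

**Elements.** Each (group, element) cell is drawn from a log-normal bridged
to the published median/IQR summaries: µ = ln(median) exactly and
σ = ln(Q3/Q1)/(2·z₀.₇₅). Zero-inflation defaults reproduce the printed
order statistics (55% zeros when the printed median is 0, 30% when only Q1
is 0), and cells whose printed summary sits at 9223.37 ng/g (Fe and Zn in
some groups) are right-censored at that value, interpreted as an
instrument/calibration ceiling. Two printed cells are internally
inconsistent (a median outside its own IQR; an inverted IQR); the shipped
table keeps the raw numbers, flags the cells, and clamps them for
simulation. The symmetric-quantile bridge cannot reproduce both quartiles
when they are strongly geometrically asymmetric about the median; for such
cells the generator preserves the median and the quartile *ratio*, and the
parameter-recovery tests distinguish the two claims accordingly.

**Spectra.** Baselines are i.i.d. log-normal per bin (median 100 counts,
sdlog 0.3) with a per-sample multiplicative TIC factor (sdlog 0.2) and
optional uniform relative mass drift for exercising lockmass correction.
The 18 marker bins are scaled by class-specific multipliers whose
directionality follows the observed biology — wild groups elevated in the
omega-3 bins (FA 20:5, FA 22:6, FA 22:1), farmed groups in the feed-oil
bins (FA 18:1/18:2/18:3), strongest in Norway. The default multipliers span
roughly 1–30 (up to ~3.4 log units between extreme groups): marker lipids
differ between production systems by orders of magnitude, and this scale
puts the class-contrast variance clearly above the noise-eigenvalue bulk
that a 5500-variable unsupervised compression must overcome at n = 500.
That is the "strong separation" regime under which the pipeline twin is
expected to classify essentially perfectly.

**What it does not emulate.** Bins and elements are independent within
class (a correlation hook exists but ships off); real spectra have
correlated isotope/adduct structure, drifting backgrounds and
heteroscedastic noise, and real element panels co-vary with diet and water
chemistry. Passing tests therefore demonstrate that the *algorithms* are
correct and that the workflow separates groups under the designed effect
structure — not that any particular accuracy will transfer to real
instrument data.

## Problem sizes and numerical notes

The test suite and the acceptance script run the pipeline twin at
n = 100/class (500 training samples, 5500 + 20 variables, five-fold CV with
per-fold re-compression), the generator-recovery checks at n = 10⁴ draws
per cell, and the outlier calibration at n = 2000; these sizes give stable
statistics in well under a minute each on a single core. Degenerate inputs
are handled explicitly: zero-variance matrices raise degenerate-input
errors, constant columns pass through scaling unscaled (min–max maps them
to 0), all-zero spectra name the offending sample, and empty marker
selections warn rather than fail. Cross-validation re-fits *every*
transform (scaling, compression, fusion) inside each training fold; the
suite asserts leak-freedom by refitting a fold's model from scratch and
reproducing the stored predictions exactly. Whether the reference workflow
re-fit its compression per fold is not documented; re-fitting is the
defensible choice, and may make these CV rates slightly conservative.

## Known limitations

- The CV-ANOVA F-approximation is labelled as such; use the permutation
  p-value for inference.
- Multi-class OPLS-DA removes variation orthogonal to the whole XᵀY span;
  other software may use per-contrast filters and report different
  orthogonal components (predictions are typically indistinguishable).
- The RF/SVM slots deliberately wrap external implementations
  (`randomForest`, `e1071`); their internals are out of scope.
- Raw vendor files are not read; ingestion starts at peak lists or binned
  matrices.
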