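---
title: "Quantifying craniocaudal visceral fat distribution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying craniocaudal visceral fat distribution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vatprofiler)
```

## The measurement problem

Visceral adipose tissue (VAT) behaves differently in the two
inflammatory bowel disease subtypes: in Crohn's disease (CD),
hyperplastic mesenteric fat accumulates around diseased — mostly ileal —
bowel segments, concentrating VAT in the lower lumbar and pelvic levels,
whereas in ulcerative colitis (UC) and in non-IBD patients the
craniocaudal VAT distribution is comparatively even. Single-slice fat
areas (the classic L3 measurement) are confounded by overall adiposity;
the *shape* of the distribution is not. The working biomarker is the
coefficient of variation (CV) of per-slice visceral fat areas across the
lumbar region: a dimensionless number that is large when fat is
concentrated at some levels and near zero when the profile is flat.

`vatprofiler` implements the whole measurement chain — phantom
simulation, rule-based segmentation, slice planning, indicator
extraction, and the discrimination statistics — as testable R functions.

## Indicators

For a VAT mask with per-slice areas $A_i$ (cm²), slice thickness $t$
(mm), total volume $V$ (cm³) and lumbar height $h$ (m, superior border
of L1 to inferior border of L5):

* **VFA** $A_i$: foreground pixel count × pixel area.
* **VAT volume** $V$: voxel count × voxel volume; identically
  $\sum_i A_i \, t/10$ over a complete tiling (a tested identity).
* **VAI** $A_i / h^2$ (cm²/m²): height-standardized area.
* **VAT ratio** $100 \, A_i (t/10) / V$ (%): the slice's share of total
  fat; sums to exactly 100% over a tiling.
* **Lumbar mean/SD/CV**: arithmetic mean, *sample* SD ($n-1$
  denominator; the conventional estimator at the $n \approx 25$–$57$
  slices involved), and $\mathrm{CV} = 100\,\mathrm{SD}/\mathrm{mean}$.

Two CV variants are computed deliberately. `lumbar_cv` uses *every
acquired slice* whose slab midpoint lies between L1-1 and L5-5;
`cv_35` uses only the 35 representative slices of the plan. Reported
values of the two differ (the representative plan also weights pelvic
levels), so they are never mixed.

## Anatomy and slice planning

Landmarks are the superior borders of L1–L5, the inferior border of L5,
and the pubic symphysis; z is measured in mm along the scanner axis,
increasing cranially, and slice $i$ (1-based) covers the half-open slab
$[(i-1)t, it)$. The plan takes $n$ slices per lumbar vertebra at the
midpoints of $n$ equal sub-bands of the vertebral span, and $m$ slices
likewise between L5-5 and the pubic symphysis; midpoint-to-grid ties
round toward the cranial side. The default split is 5 × 5 lumbar + 10
pelvic = 35 slices labelled `L1-1`…`L5-5`, `Pelvis-1`…`Pelvis-10`. The
total is the established choice; the per-region split is not uniquely
determined by the labelling scheme, so both counts are arguments rather
than constants.

## Segmentation model

The rule-based segmentation mirrors standard body-composition practice:

1. **Fat window.** A voxel is fat iff its attenuation lies in
   $[-190, -30]$ HU (inclusive; configurable). This is the de-facto
   standard adipose window on calibrated CT.
2. **Body.** Largest 26-connected component above −500 HU, cavities
   filled by flood-fill from the volume border (6-connectivity on the
   background complements 26-connectivity on the foreground).
3. **VAT/SAT split.** The body's boundary shell is the body minus its
   6-neighbourhood erosion iterated `shell_voxels` times (default 2).
   Fat components (26-connected) touching the shell are subcutaneous;
   the rest are visceral. A component bridging both regions goes to SAT
   — a deterministic, traversal-order-independent tie-break.

These kernels are compiled (Rcpp) — stack-based flood fills and
erosions over ~4 × 10⁶-voxel volumes, the same place imaging packages
put their inner loops.

Dice and Jaccard are reported together; they are algebraically locked
($D = 2J/(1+J)$, also a tested identity). Two empty masks score 1
(perfect agreement), empty vs non-empty scores 0.

## The phantom generator

The phantom emulates what the analysis assumes about abdominal CT, not
abdominal anatomy at large: an elliptical body (default semi-axes
115 × 80 mm) with a 15 mm subcutaneous fat annulus directly under the
surface, a 10 mm muscle wall, a posterior vertebral rod (+400 HU), and
visceral fat blobs in the remaining cavity; tissue means VAT −100, SAT
−105, muscle +40, air −1000 HU with additive Gaussian noise of SD 10 HU
(all configurable). Both fat compartments sit inside the fat window and
everything else at least 7 noise-SDs outside it, which is why
segmentation recovery is essentially exact on phantoms — passing those
tests validates the machinery, not clinical-grade robustness to real
CT, where partial-volume voxels, bowel content and contrast enhancement
blur the window boundaries. Default resolution is 1 × 1 mm in-plane
with 3 mm slices, the coarsest slice thickness in routine abdominal
protocols.

The craniocaudal profile is specified on the normalized coordinate
$u \in [0,1]$ from the superior border of L1 ($u=0$) to the pubic
symphysis ($u=1$):

* `uniform` — constant density (lumbar CV ≈ 0);
* `beta` — density $\propto u^c$, a Beta$(c+1, 1)$ density; the
  concentration $c$ shifts mass caudally, and the induced lumbar CV is
  strictly increasing in $c$ (tested over a grid of 6 values);
* `linear` — density $1 + c(u - \tfrac12)$, $c \le 2$ for
  non-negativity.

Per-slice target areas are the profile weights scaled to the requested
total volume; each slice is filled with exactly that number of cavity
pixels, chosen nearest-first to a seeded set of blob centres (random
centres, random per-blob radius weights, distance ties broken by pixel
order). Area realization is therefore exact up to per-slice rounding —
total-volume error is far below the 2% voxelization tolerance — while
the blob geometry stays coherent across slices. All randomness flows
from the spec's single seed, and equal specs give bit-identical
volumes.

What the phantom does *not* model: organs, bowel gas, creeping-fat
microstructure, contrast phases, scanner-specific noise spectra. Tests
passing on phantoms certify the pipeline's arithmetic and invariances;
they say nothing about segmentation accuracy on patient scans.

## Cohort simulation

`simulate_cohort()` draws per-subject variables independently within
groups: continuous variables from normal distributions, binary ones
from Bernoulli. `default_cohort_spec()` carries the published
case-control marginals (CD n=365, UC n=241, appendicitis controls
n=166; e.g. automatic-arm CV 29.73 ± 14.67% for CD vs 26.23 ± 12.47%
for UC). Variables reported as median (IQR) are normal-approximated
with mean = median and SD = IQR/1.349 — adequate for age, crude for
right-skewed CRP/ESR, which is acceptable because nothing downstream
assumes those margins beyond group contrasts. No inter-variable copula
is modelled: only marginals are published, and the discrimination
checks need only the group structure.

## Statistics

* **Two groups:** equal-variance Student t or Mann-Whitney (normal
  approximation with mid-ranks); `auto` selects nonparametric when
  Shapiro-Wilk (α = 0.05, per group; order-statistic subsample above
  n = 5000) rejects in either group. χ² for categorical data, Yates
  correction only when a 2×2 has an expected count < 5.
* **Three groups:** one-way ANOVA or Kruskal-Wallis, then the three
  pairwise contrasts each judged at the Bonferroni-corrected
  α = 0.05/3 = 0.0167 (a pairwise p of 0.03 is *not* significant).
* **Logistic regression:** `stats::glm`, Wald 95% CIs on odds ratios,
  listwise deletion, separation flagged heuristically (|coef| > 15,
  SE > 100, or fully saturated fitted probabilities). A CV covariate
  can enter on the percent or the fraction scale (`cv_scale`); the
  per-unit odds ratio differs by a factor $e^{\beta}$ vs
  $e^{\beta/100}$, which matters when comparing published ORs.
* **ROC:** AUC as the normalized Mann-Whitney statistic from mid-ranks
  (ties count ½) — verified against brute-force pair enumeration — with
  DeLong structural-component variance for the CI; the operating point
  maximizes the Youden index over `score ≥ c` cutoffs, ties broken
  toward higher specificity (fixed, so results are reproducible; the
  high-specificity operating point is the clinically conservative one
  for a rule-in biomarker).
* **DeLong comparison:** paired structural components, z-test on the
  AUC difference; rank-equivalent classifiers give difference 0 and
  p = 1 by convention (the variance estimate degenerates to 0).

The implementation of AUC/DeLong is cross-checked in the test suite
against `pROC` on random fixtures, and the DeLong variance against a
stratified bootstrap (10⁵ resamples) on a frozen n = 10 fixture.

## Numerical and design choices

* Voxel traversal order never affects results: connected-component
  labels are assigned in column-major scan order, distance ties in the
  phantom use pixel order, Youden ties a fixed rule.
* CSV output serializes doubles as `%.17g` (bit-exact round-trip);
  NIfTI volumes are written as float64 and masks as uint8, preserving
  values and voxel spacing exactly.
* Degenerate inputs fail loudly: empty bodies, fat outside the body,
  one-class ROC labels, zero lumbar height, zero-volume VAT ratios, and
  all-zero area vectors (CV flagged `NA`) all raise or warn.
* The pipeline's provenance (package version, seed, MD5 of the
  scientific config — output paths excluded) is embedded in every CSV;
  reruns with equal config and seed are byte-identical.

Problem sizes in the shipped checks are chosen to keep a full run
routine on a laptop: unit tests use 2 × 2 × 6 mm phantoms
(120 × 92 × 52 voxels), while the acceptance checks run the study-scale
1 × 1 × 3 mm geometry (240 × 176 × 104) for the Dice/CV recovery and
a 6-point concentration grid, 500 simulated cohorts for the CV-AUC,
2000 null replicates for t-test calibration and 200 for logistic CI
coverage (n = 600, true OR 6 on a standardized covariate — a balanced
design where the Wald approximation is at its cleanest).

## Known limitations

* The rule-based segmentation is a transparent re-specification of
  semi-automatic body-composition practice, not a reproduction of any
  operator protocol, and no deep-learning segmentation is included.
* Real cohort-level results (published Table-2 means, OR = 6.05,
  AUC = 0.811) depend on patient CT volumes that are not publicly
  deposited; the package reproduces exactly the printed
  contingency-derived quantities and checks distribution-level
  statistics against simulation, nothing more.
* The phantom's monotone concentration → CV link makes it a clean test
  bed, but effect sizes on phantoms are not calibrated to clinical
  effect sizes.
* Covariate coding for multivariable models (age categorization,
  CRP/ESR transforms) is configurable rather than asserted, since no
  canonical coding is established.
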