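# vatprofiler

Craniocaudal profiling of visceral adipose tissue (VAT) in abdominal CT,
for imaging researchers studying fat distribution as a biomarker — in
particular for distinguishing the inflammatory bowel disease subtypes
Crohn's disease (CD) and ulcerative colitis (UC), where CD is
characterized by mesenteric fat concentrated in the lower lumbar levels
while UC and non-IBD controls show a near-uniform distribution.

The package provides the full measurement chain:

* **Synthetic CT phantoms** — elliptical body, subcutaneous fat annulus,
  visceral fat blobs with a controllable craniocaudal profile, vertebral
  landmarks, realistic Hounsfield units with Gaussian noise, and
  ground-truth masks, so every downstream stage is testable without
  patient data.
* **Rule-based segmentation** — fat by HU windowing (default −190 to
  −30 HU), body extraction by connected components and hole filling, and
  VAT/SAT separation by body-shell connectivity; Dice/Jaccard overlap
  scoring.
* **Anatomy** — representative slice planning (5 slices per lumbar
  vertebra + 10 pelvic = 35 by default) from vertebral landmarks, and
  the lumbar height `h` between the superior border of L1 and the
  inferior border of L5.
* **Indicators** — per-slice visceral fat area (VFA, cm²), total VAT
  volume (cm³), visceral adipose index `VAI = VFA / h²` (cm²/m²), slice
  share `VAT ratio (%) = VFA × thickness / volume × 100`, and the lumbar
  mean, SD and coefficient of variation `CV (%) = SD / mean × 100` of
  per-slice VFAs — the candidate biomarker.
* **Statistics** — Student-t / Mann-Whitney / χ² two-group comparisons,
  ANOVA / Kruskal-Wallis with pairwise follow-ups at the corrected level
  α = 0.05/3 = 0.0167, logistic regression with Wald odds-ratio CIs, ROC
  analysis with the Youden operating point, and DeLong's test for
  correlated AUCs.

## Worked example

A binary predictor evaluated exactly from a published-style 2×2 table
(perianal disease: 129/344 CD patients, 18/237 UC patients):

```r
library(vatprofiler)
labels   <- rep(c("CD", "UC"), c(344, 237))
perianal <- c(rep(1, 129), rep(0, 215), rep(1, 18), rep(0, 219))
roc_analysis(labels, perianal, positive = "CD")
#> AUC 0.650 [0.619, 0.680]; sensitivity 37.50%, specificity 92.41% at cutoff 1
```

For a binary score the AUC equals (sensitivity + specificity)/2: here
(37.50 + 92.41)/200 = 0.650 — the perianal predictor identifies barely a
third of CD cases but almost never misclassifies UC.

A phantom with caudally concentrated fat, segmented and profiled:

```r
ph  <- generate_phantom(phantom_spec(
  vat_profile = profile_spec("beta", 0.6), seed = 42))
seg <- segment_vat(ph$volume)
overlap_scores(seg$vat, ph$masks$vat)
#> Dice 1.0000, Jaccard 1.0000
subject_metrics(seg$vat, ph$landmarks)
#> <subject_metrics> VAT volume 1500.0 cm^3, lumbar mean 42.24 cm^2,
#>   SD 17.22 cm^2, CV 40.77% (CV over 35 representative slices: 42.50%)
```

The concentration parameter of the phantom's profile maps monotonically
to the lumbar CV, so graded phantom cohorts emulate the CD-vs-UC
contrast. An end-to-end seeded run over three simulated groups:

```r
cfg <- read_config(system.file("extdata", "demo_config.json",
                               package = "vatprofiler"))
run_pipeline(cfg)$report
#>   indicator             CD             UC        control p_omnibus ...
#> 1      mean 35.58 +/- 7.35 42.65 +/- 4.72 55.98 +/- 6.56   0.00407
#> 2        sd 14.48 +/- 1.46 10.02 +/- 2.32 12.20 +/- 1.68   0.02403
#> 3        cv 41.95 +/- 9.67 23.77 +/- 6.48 22.15 +/- 4.96   0.00697
```

The CD-like group shows the highest CV while UC-like and control-like
groups are similar — the distribution signature the CV biomarker
captures. A thin CLI over the same functions is installed at
`inst/scripts/vat-profiler`
(`simulate | segment | plan-slices | metrics | analyze | run`).

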