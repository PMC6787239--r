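---
title: "Detecting microcalcification clusters in digitised mammograms and linking them to short-term risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting microcalcification clusters in digitised mammograms and linking them to short-term risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammocalc)
```

## The problem

Microcalcifications are small deposits of calcium oxalate and calcium
phosphate in breast tissue that appear as bright specks of roughly 0.1–1 mm
on a mammogram. Spatially dense groups of them — clusters — are of
epidemiological interest beyond cancer detection: even on a *negative*
screening mammogram, the number of microcalcification clusters carries
information about a woman's short-term risk of invasive breast cancer.
Quantifying that association at scale requires an automated detector that
works on digitised screen-film mammograms, which are noisier and differently
contrasted than modern digital images, and a statistical workflow that
relates per-woman cluster counts to case-control status and to established
risk factors.

`mammocalc` implements both halves: a three-step image pipeline
(preprocessing, candidate detection, cleaning and grouping), and the
case-control statistics (adjusted logistic regression, likelihood-ratio
tests, bootstrap-optimism-corrected AUC, age-adjusted risk-factor scans).
Because clinical film archives cannot be redistributed, the package also
ships seed-deterministic generators for phantom mammograms with ground-truth
annotations and for synthetic cohorts with known effect sizes; every claim
the test suite makes is checked against those generators.

## The image pipeline

### Breast-profile segmentation

Film digitisations contain the breast, film labels and tags, and dark
background. Segmentation proceeds by (1) a logarithmic transform
`log(1 + I/I_max)` that brightens low intensities near the skin line (the
`+1` avoids `log 0`; Otsu partitions are invariant to the overall scale);
(2) three-class Otsu thresholding — an exhaustive search over pairs of
thresholds on a 256-bin histogram maximising between-class variance — of
which the union of the two brightest classes is kept (the darkest class is
background); (3) the largest connected component (labels are smaller,
disjoint objects); (4) binary closing then opening with a disk of radius
5 px and hole filling. The closing-then-opening order fills small inlets
before removing protrusions; the radius and the class count are
config-exposed (`preprocess$mask_smooth_radius_px`).

A constant-intensity image has no Otsu partition and raises
`"no foreground found"`.

### Denoising

Digitisation adds dust/artefact specks and mixed Poisson–Gaussian noise.
The pipeline applies:

1. **Grayscale opening** with a disk of one pixel radius (the 3×3
   plus-shaped neighbourhood), deleting single-pixel bright dust while
   preserving structures of 2 px and larger.
2. **The Anscombe transform** `y = 2*sqrt(x + 3/8)`, which approximately
   maps Poisson noise to unit-variance Gaussian noise.
3. **A locally adaptive Wiener filter** in the Anscombe domain: with local
   mean `m` and variance `v` over a `w × w` window (default `w = 5`) and a
   global noise floor `s²` estimated as the mean of the local variances
   inside the breast mask, the output is `m + max(v − s², 0)/v · (x − m)`.
   Flat regions collapse to their local mean; structured regions pass
   through.
4. **The algebraic inverse Anscombe** `x = (y/2)² − 3/8`, clipped at zero.
   The exact unbiased inverse differs only at very low counts; film
   intensities live at levels where the algebraic inverse's bias is
   negligible, and the closed form keeps the round trip exact to 1e−9 on
   noise-free values.

### Enhancement

Microcalcifications are among the brightest objects inside the breast, so a
**cosine intensity stretch** `T(x) = 1 − cos(πx/2)` is applied to min-max
normalised intensities within the mask. `T` is strictly increasing with
`T(0) = 0`, `T(1) = 1`, and has an increasing derivative: it contracts the
lower gray levels and spreads the upper ones. (The literature states the use
of a cosine-based stretch without printing the formula; this realisation has
the stated qualitative behaviour and is documented here as the package's
convention.)

A **difference-of-Gaussians band-pass** then isolates the
microcalcification size band. Speck diameters of 0.1–1 mm at 0.05 mm/px are
2–20 px, motivating `σ_low = 1 px`, `σ_high = 8 px`. Negative responses are
clipped (dark spots are irrelevant) and the response is rescaled to [0, 1]
over the mask. All Gaussian filtering uses replicated borders — circular
convolution would wrap the breast into the background at the chest-wall
edge and synthesise spurious transitions.

### Candidate detection

At scale `σ = 2 px` (mid-band), the γ-normalised Hessian (γ = 2, i.e.
multiplied by σ²) is computed at every pixel and its eigenvalues
`λ1, λ2` (`|λ1| ≤ |λ2|`) obtained in closed form. Bright blobs have two
similar negative eigenvalues; bright ridges have `λ1 ≈ 0`, `λ2 < 0`. Two
maps are formed:

* `blob_map = |λ2| · exp(−(λ1/λ2 − 1)²/0.5)` where both eigenvalues are
  negative;
* `line_map = |λ2| · exp(−(λ1/λ2)²/0.5)` where `λ2 < 0`.

The line kernel is deliberately *soft*: a hard eigenvalue-ratio cutoff
(`|λ1| < 0.25 |λ2|`) turns off at ridge bends and junctions, exactly where
vetoing is needed. Both maps are divided by the same constant (the blob
maximum) so that a pixel's line response is directly comparable with its
blob response; a per-map normalisation would inflate the line scale in
images that contain no ridge at all.

Candidates are pixels above an adaptive threshold, `mean + k·sd` of the
non-zero blob responses inside the mask (`k = 3`), grouped by
8-connectivity and measured (area, centroid, eccentricity, axis lengths,
mean responses). Candidates within 1 mm of the skin line are discarded
(`detect$skin_margin_mm`): the breast/background transition produces
band-pass responses that no shape rule reliably rejects, and the response
of the wider DoG Gaussian (`σ_high = 8 px`) to the boundary step only
decays to a few percent about 2.5 σ ≈ 1 mm inside the mask.

### Cleaning and grouping

The cleaning step removes objects unlike microcalcifications:

* area outside 2–80 px (≈ 0.07–0.45 mm equivalent diameter);
* eccentricity above 0.95;
* mean line response over the spot at or above 0.5;
* **contact with a long linear structure**: the line map is binarised at
  0.5, connected components with major axis ≥ 2 mm are dilated by 3 px, and
  any candidate touching them is removed. The length scale comes from the
  biology — a single calcification is at most about 1 mm, so a contiguous
  high-line structure of 2 mm or more must be a vessel or fibrous strand.
  This rule is what actually removes noise-driven "beads" along vessels:
  each bead is locally compact and passes every per-spot test. Beaded
  arterial calcifications *away* from a contiguous ridge response still
  pass, which is intended — the detector counts all calcifications,
  arterial ones included.

Survivors are grouped with **DBSCAN** on centroids in millimetres
(`eps = 5 mm`, `minPts = 3`, the clinical convention of at least three
calcifications within about a square centimetre). DBSCAN noise points are
the discarded isolated spots; isolated calcifications are not clinically
significant. Spots are sorted by (row, col) before clustering and clusters
are grown in that order, so border points always join the earliest-seeded
reachable cluster and the partition is invariant to input permutation.

The pipeline applies one cluster-level sanity rule on top of plain DBSCAN
(`cluster$max_hull_cm2 = 3`): groups whose convex hull exceeds 3 cm² are
dissolved and their spots reclassified as discarded noise. Density-based
clustering *chains*: at the spot densities residual noise can reach, the
whole breast links into a single sprawling "cluster" with a hull of
hundreds of cm². A clinical microcalcification cluster is a compact group
of roughly a square centimetre; a breast-wide scattering is the
diffuse/scattered distribution, a different (and typically benign)
category that the cluster count must not include. True clusters in the
phantoms have hulls of ~13 mm², fifty-fold below the bound. The raw
`dbscan_group()` keeps the textbook behaviour (`max_hull_mm2 = Inf`), so
its brute-force oracle equivalence is over plain DBSCAN.

The per-woman exposure is the total cluster count over the left and right
MLO views; a missing side excludes the woman.

## The statistical workflow

`fit_logistic()` wraps a maximum-likelihood logistic fit (IRLS via `glm`)
with the package's reporting conventions: complete-case analysis,
reference levels HRT = never / smoking = never / diabetes = no, odds
ratios with Wald 95% CIs, and per-term p-values from likelihood-ratio
tests. Perfect separation and singular designs are explicit errors naming
the offending covariate.

Because breastfeeding and age at first birth exist only for parous women,
`build_reproductive_covariate()` combines parity, breastfeeding and AFB
into one 9-level factor: nulliparous; parous × {never, ever breastfed} ×
AFB strata {< 23, 23–27, > 27 years}; and two levels for parous women with
known breastfeeding but missing AFB. Parous women with missing
breastfeeding are flagged for exclusion. The AFB strata and the level
composition are package conventions (the source analyses did not print
them) and are config-overridable.

`honest_auc()` implements bootstrap internal validation: the apparent
c-statistic (ties counted ½) minus the mean bootstrap optimism, where each
optimism draw is the refitted model's AUC on its resample minus its AUC on
the original data. Resamples with a single outcome class or non-convergent
fits are redrawn (capped at 5× the requested resamples). A covariate that
separates the outcome perfectly short-circuits to
apparent = honest = 1.

`riskfactor_scan()` fits one age-adjusted logistic model per risk factor on
controls only, with cluster *presence* (0 vs 1+) as the outcome — counts
are too sparse among unaffected women for multinomial modelling — and
reports OR, CI, LRT p and a Bonferroni flag at a family size of 11
(deliberately conservative).

## The synthetic generators

### Phantoms

`make_phantom()` renders: a half-elliptical breast entering from the left
(chest-wall) edge at 0.05 mm/px; a smooth Gaussian background texture
(sd 8 counts, correlation length 30 px) on a base level of 100 counts;
bright film labels outside the breast; Gaussian specks of stated diameter
and amplitude; curvilinear ridges; and Poisson(x·s)/s plus Gaussian read
noise (sd 2). The Poisson component at level 100 justifies the Anscombe
step. The default geometry is 1024 × 768 px — a desk-scale stand-in for
full 4770 × 3580 film scans that preserves all physical scales (mm sizes
are converted through the same spacing).

`random_phantom_spec()` encodes the benchmark conditions: 3 clusters of 4
specks (diameters 0.2–0.6 mm) within 2 mm of their centre, speck amplitude
78 counts = 6× the effective background standard deviation
(`sqrt(8² + 100 + 2²) ≈ 13`, combining texture, shot noise at the
background level, and read noise), two isolated specks, one vessel-like
ridge of the same amplitude. Cluster centres sit ≥ 3.5 mm inside the breast
boundary and ≥ 12 mm apart (clusters cannot merge under the 5 mm grouping
radius once centres are > 9 mm apart); specks within a cluster are ≥ 1.2 mm
apart, because two fused deposits read as a single elongated — line-like —
object. The annotation's "true clusters" are DBSCAN (5 mm, 3) on the true
centres, so generator and detector share one cluster definition.

What the phantoms do *not* emulate: anatomical tissue structure
(ducts, parenchymal texture at intermediate scales), scanner
optical-density calibration, pectoral muscle, and the full film geometry.
Passing the detection suite therefore demonstrates correct behaviour of the
algorithm under controlled contrast and noise, not clinical-grade accuracy
on real film.

### Cohorts

`make_cohort()` draws covariates from marginals calibrated to the published
control characteristics of the CAHRES short-term risk study (postmenopausal
Swedish women aged 50–74): age N(63.8, 6.1), BMI N(25.5, 3.9), percent
density Gamma with mean 14.6 and sd 13.7 (right-skewed, capped at 100), HRT
(never/past/current) at 78.6/3.1/18.3%, parity Poisson(2.163), smoking
40.4% ever, diabetes 5.3%, age at menopause N(50.2, 4.1); among parous
women, AFB N(24.9, 4.7), breastfeeding 93.9% ever, duration Gamma with mean
11.7 and sd 10.3 months.

Cluster counts follow a zero-modified (hurdle) count model: presence is
Bernoulli with `logit P(≥1) = logit(0.27) + log(1.060)·(age − 63.8)`, and
positive counts are `1 + Poisson(0.6)`. The hurdle form was chosen over a
classical zero-inflated Poisson because it calibrates `P(≥1) = 0.27`
exactly and makes presence *exactly* logistic in age, which is the
estimand of the control-only risk-factor scan.

Case status follows a logistic model whose default log-odds are the
adjusted estimates of the reference analysis (per-cluster OR 1.306, HRT
current 2.274, PD 1.022 per percent, and so on). The intercept is solved
numerically for a population prevalence of 2%; in that rare-disease regime
case-control sampling leaves the control marginals essentially at their
calibration targets (at higher prevalences the controls are measurably
depleted of high-percent-density women) while the sampled odds ratios
remain the conditional ones. Missingness is applied to the reproductive trio at rates chosen so
that the 9-level covariate's complete-case cohort reproduces the published
second-model sizes (≈ 210 cases / 605 controls); the published per-factor
complete-case Ns cannot all be hit simultaneously under this exclusion
rule, and the model-2 sizes were preferred because they are the ones a
refit depends on.

## Numerical choices and degenerate inputs

* Problem sizes: phantoms are evaluated at 1024 × 768 over 20 seeds;
  parameter recovery uses 200 cohorts of 981 women; optimism calibration
  uses 50 replicates at 100 bootstrap resamples (the reference analysis
  used 1000 resamples; optimism means stabilise well below that, and the
  production default in `mc_config()` remains 1000).
* Ties in the c-statistic count ½; `rank()` implements this exactly.
* DBSCAN neighbourhoods include the point itself (`minPts` counts the
  point), matching the common implementation convention.
* The Otsu search requires at least three occupied histogram classes;
  constant or two-valued degenerate images raise errors rather than
  returning empty masks.
* Convex-hull areas of collinear clusters are 0 by the shoelace formula.
* All generators and the bootstrap consume explicit integer seeds and are
  bit-for-bit reproducible.

## Known limitations

* The detector runs at a single Hessian scale (σ = 2 px); very large
  (≈ 1 mm) or sub-0.1 mm calcifications respond suboptimally. Multi-scale
  pyramids were deliberately left out of scope.
* The linear-structure veto can, in principle, suppress a genuine
  calcification lying directly on a vessel; on phantoms this was never
  observed, but real BAC-adjacent clusters may be undercounted.
* Percent density is consumed as a covariate, never computed; film
  calibration and pectoral-muscle removal are out of scope.
* The 9-level reproductive covariate and the AFB strata are conventions;
  refits against data coded with different strata will differ in the
  category-level estimates (not in the cluster-count term, which is the
  quantity of interest).
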