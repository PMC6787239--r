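# mammocalc

Detection of microcalcification clusters in digitised screen-film
mammograms, and case-control analysis of their association with short-term
invasive breast-cancer risk.

Microcalcifications — calcium oxalate/phosphate deposits of ~0.1–1 mm that
show up as bright specks — are not only a detection cue for cancer: the
number of microcalcification *clusters* on an otherwise negative mammogram
is associated with a woman's risk of developing invasive breast cancer
within the following two years. Studying that association in large film
archives needs (a) an automated detector robust to digitisation noise and
(b) the epidemiological machinery to relate per-woman counts to outcomes.
`mammocalc` provides both, plus seed-deterministic phantom and cohort
generators so the whole pipeline is testable without clinical images.

## The algorithm

Per image (one MLO view), three steps:

1. **Preprocessing** — breast-profile segmentation (logarithmic transform,
   3-class Otsu thresholding keeping the two brightest classes, largest
   connected component, morphological smoothing); dust removal by grayscale
   opening (disk, radius 1 px); denoising by an adaptive Wiener filter in
   the Anscombe domain (`y = 2·sqrt(x + 3/8)`), where mixed
   Poisson–Gaussian film noise is approximately stationary Gaussian.
2. **Candidate detection** — cosine intensity stretch
   `T(x) = 1 − cos(πx/2)` of the upper gray levels; difference-of-Gaussians
   band-pass (σ = 1 and 8 px at 0.05 mm/px) matched to speck sizes;
   Hessian-of-Gaussian eigenvalue analysis (γ-normalised, σ = 2 px) giving
   a blob map and a line map; adaptive thresholding at mean + 3·sd.
3. **Cleaning and grouping** — size/eccentricity filters, a line veto
   (including removal of candidates touching contiguous line structures
   longer than 2 mm — vessels, not calcifications), then DBSCAN on spot
   centroids (eps = 5 mm, minPts = 3). Isolated spots are discarded;
   the per-woman exposure is the total cluster count over both breasts.

Per cohort: adjusted logistic regression of case-control status on the
cluster count (odds ratios with Wald CIs, likelihood-ratio p-values),
Harrell bootstrap optimism-corrected ("honest") AUC with and without the
cluster term, a 9-level parity × breastfeeding × age-at-first-birth
covariate for the fully adjusted model, and age-adjusted one-factor-at-a-time
scans of risk factors against cluster presence in controls.

## Worked example

```r
library(mammocalc)

# a phantom film mammogram: 3 speck clusters, 2 isolated specks, a vessel
ph  <- make_phantom(random_phantom_spec(seed = 1))
det <- detect_clusters(ph$image)
det
#> <mc_detection> 42 candidates -> 14 after cleaning -> 3 cluster(s) (2 isolated)
ph$annotation$n_clusters
#> [1] 3

# a synthetic case-control cohort at the published effect sizes
co  <- make_cohort(cohort_spec(seed = 1))
fit <- fit_logistic(co, "status",
                    c("age_yr", "bmi_kg_m2", "pd_percent", "hrt", "parity",
                      "smoking", "diabetes", "age_menopause_yr", "mcc_total"))
fit$table[fit$table$term == "mcc_total", c("or", "or_lo", "or_hi", "p_lrt")]
#>          or    or_lo    or_hi       p_lrt
#> 11 1.281821 1.094914 1.500633 0.002353263
```

The detector found the three injected clusters and discarded the two
isolated specks; the cohort fit recovers a per-cluster odds ratio near the
generative value 1.306 (single-replicate sampling error is ~±0.1; the mean
over 200 replicates is within 3%).

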