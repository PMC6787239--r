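Package: mammocalc
Title: Microcalcification Cluster Detection and Short-Term Risk Analysis for
    Digitised Mammograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects and groups microcalcification clusters in digitised
    screen-film mammograms using a three-step pipeline (breast-profile
    segmentation with multilevel Otsu thresholding and Anscombe-domain
    adaptive Wiener denoising; cosine intensity stretching with
    difference-of-Gaussians band-pass enhancement; Hessian-of-Gaussian blob
    detection with shape filtering and DBSCAN grouping), and links per-woman
    cluster counts to short-term invasive breast-cancer risk through
    case-control logistic regression, likelihood-ratio tests,
    bootstrap-optimism-corrected ("honest") AUC, and age-adjusted risk-factor
    scans. Includes seed-deterministic generators for phantom mammograms with
    ground-truth annotations and for synthetic case-control cohorts, so the
    whole pipeline is testable without access to clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    rlang,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
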