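#' Default pipeline configuration
#'
#' All tunable parameters of the detection pipeline and the statistical
#' workflow, as one nested list. Override values with `overrides` (a nested
#' list) or a YAML file; unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param overrides nested list of overrides, e.g.
#'   `list(detect = list(k_sigma = 4))`.
#' @param yaml_path optional path to a YAML file of overrides.
#' @return nested list of class `mc_config`, with a `config_hash` attribute
#'   echoed into every output artifact.
#' @export
mc_config <- function(overrides = NULL, yaml_path = NULL) {
  cfg <- list(
    spacing_mm = 0.05,
    preprocess = list(
      otsu_classes = 3,
      mask_smooth_radius_px = 5,
      wiener_window = 5
    ),
    enhance = list(
      dog_sigma_low_px = 1,
      dog_sigma_high_px = 8
    ),
    detect = list(
      hessian_sigma_px = 2,
      line_scale = 0.5,
      k_sigma = 3,
      skin_margin_mm = 1
    ),
    cluster = list(
      min_area_px = 2,
      max_area_px = 80,
      max_eccentricity = 0.95,
      line_veto = 0.5,
      line_length_mm = 2,
      eps_mm = 5,
      min_pts = 3,
      max_hull_cm2 = 3
    ),
    stats = list(
      n_boot = 1000,
      seed = 1,
      afb_breaks = c(23, 27),
      bonferroni_family = 11
    )
  )
  if (!is.null(yaml_path)) {
    overrides <- utils::modifyList(yaml::read_yaml(yaml_path),
                                   overrides %||% list())
  }
  if (!is.null(overrides)) {
    check_known_keys(overrides, cfg, path = "")
    cfg <- utils::modifyList(cfg, overrides)
  }
  if (cfg$preprocess$otsu_classes != 3)
    stop("only 3 Otsu classes are supported")
  attr(cfg, "config_hash") <- rlang::hash(cfg)
  class(cfg) <- "mc_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_known_keys <- function(given, reference, path) {
  for (nm in names(given)) {
    if (!nm %in% names(reference))
      stop("unknown config key: ", paste0(path, nm))
    if (is.list(given[[nm]]) && is.list(reference[[nm]]))
      check_known_keys(given[[nm]], reference[[nm]], paste0(path, nm, "."))
  }
}

#' Run the full detection pipeline on one image
#'
#' Chains the three algorithm steps on a single digitised mammogram:
#' (1) preprocessing -- breast-profile segmentation, opening + Anscombe-domain
#' adaptive Wiener denoising, cosine intensity stretch, DoG band-pass;
#' (2) candidate detection -- Hessian-of-Gaussian blob/line responses and
#' adaptive thresholding; (3) cleaning and grouping -- shape/size/line-veto
#' filtering and DBSCAN clustering.
#'
#' @param img a [mammogram()] or a path readable by [read_mammogram()].
#' @param config a [mc_config()].
#' @return list of class `mc_detection`: `clusters` (a `cluster_set`),
#'   `spots` (surviving candidate data.frame), `mask`, `counts` (per-stage
#'   candidate counts), `config_hash`.
#' @export
detect_clusters <- function(img, config = mc_config()) {
  if (is.character(img)) img <- read_mammogram(img, config$spacing_mm)
  mask <- segment_breast(img, config$preprocess$mask_smooth_radius_px)
  den <- denoise(img, mask, config$preprocess$wiener_window)
  str <- cosine_stretch(den, mask)
  enh <- dog_filter(str, config$enhance$dog_sigma_low_px,
                    config$enhance$dog_sigma_high_px, mask)
  hr <- hessian_response(enh, config$detect$hessian_sigma_px,
                         config$detect$line_scale)
  # candidates are only accepted away from the skin line, where the
  # breast/background transition produces spurious band-pass responses
  cand_mask <- mask
  margin_px <- round(config$detect$skin_margin_mm / img$spacing_mm)
  if (margin_px > 0) {
    er <- erode_zero_pad(mask$mask, margin_px)
    if (sum(er) > 0) cand_mask <- breast_mask(er)
  }
  cand <- threshold_candidates(hr$blob_map, cand_mask, config$detect$k_sigma,
                               line_map = hr$line_map)
  filt <- shape_filter(cand,
                       min_area_px = config$cluster$min_area_px,
                       max_area_px = config$cluster$max_area_px,
                       max_eccentricity = config$cluster$max_eccentricity,
                       line_map = hr$line_map,
                       line_veto = config$cluster$line_veto,
                       line_length_mm = config$cluster$line_length_mm,
                       spacing_mm = img$spacing_mm)
  cs <- dbscan_group(filt$spots, eps_mm = config$cluster$eps_mm,
                     min_pts = config$cluster$min_pts,
                     spacing_mm = img$spacing_mm,
                     max_hull_mm2 = config$cluster$max_hull_cm2 * 100)
  structure(
    list(clusters = cs, spots = filt$spots, mask = mask,
         counts = list(
           n_candidates = nrow(cand),
           n_filtered_by_shape = filt$n_removed_area + filt$n_removed_ecc +
             filt$n_removed_line,
           n_after_filter = nrow(filt$spots),
           n_clusters = cs$n_clusters,
           n_isolated_discarded = cs$n_isolated_discarded
         ),
         config_hash = attr(config, "config_hash")),
    class = "mc_detection"
  )
}

#' @export
print.mc_detection <- function(x, ...) {
  cat(sprintf(
    "<mc_detection> %d candidates -> %d after cleaning -> %d cluster(s) (%d isolated)\n",
    x$counts$n_candidates, x$counts$n_after_filter, x$counts$n_clusters,
    x$counts$n_isolated_discarded))
  invisible(x)
}

detection_json <- function(det, image_id, spacing_mm) {
  list(
    image_id = image_id,
    config_hash = det$config_hash,
    n_clusters = det$counts$n_clusters,
    clusters = lapply(det$clusters$clusters, function(cl) {
      list(centroid_mm = round(cl$centroid_rc * spacing_mm, 3),
           n_spots = cl$n_spots,
           hull_area_mm2 = round(cl$hull_area_mm2, 3))
    }),
    n_isolated = det$counts$n_isolated_discarded,
    n_filtered = det$counts$n_filtered_by_shape
  )
}

#' Detect clusters over a directory of paired-view mammograms
#'
#' Runs [detect_clusters()] on every image, pairs left/right views by the
#' filename convention `{id}_L.*` / `{id}_R.*`, and writes one JSON per
#' image plus a cohort CSV with one row per woman
#' (`id, n_clusters_left, n_clusters_right, mcc_total`). Unpaired images are
#' excluded with a warning (the study design requires both MLO views);
#' unreadable images are logged and skipped.
#'
#' @param paths directory or vector of image paths.
#' @param config a [mc_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the cohort data.frame.
#' @export
detect_directory <- function(paths, config = mc_config(),
                             out_dir = "mc_output") {
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(tif|tiff|png|pgm)$",
                        ignore.case = TRUE, full.names = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- sub("\\.[^.]+$", "", basename(paths))
  side <- toupper(sub("^.*_([LlRr])$", "\\1", base))
  id <- sub("_[LlRr]$", "", base)
  valid <- side %in% c("L", "R") & side != base
  if (any(!valid)) {
    warning("excluded (no _L/_R suffix): ",
            paste(basename(paths[!valid]), collapse = ", "))
  }
  results <- list()
  failed <- character(0)
  for (i in which(valid)) {
    det <- tryCatch(detect_clusters(paths[i], config), error = function(e) {
      message("skipping unreadable/failed image ", basename(paths[i]), ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(det)) { failed <- c(failed, paths[i]); next }
    jsonlite::write_json(
      detection_json(det, base[i], config$spacing_mm),
      file.path(out_dir, paste0(base[i], ".json")),
      auto_unbox = TRUE, pretty = TRUE)
    results[[paste(id[i], side[i], sep = "|")]] <- det$counts$n_clusters
    message(sprintf("%s: %d candidates, %d clusters", base[i],
                    det$counts$n_candidates, det$counts$n_clusters))
  }
  ids <- unique(id[valid])
  rows <- list()
  for (w in ids) {
    l <- results[[paste(w, "L", sep = "|")]]
    r <- results[[paste(w, "R", sep = "|")]]
    if (is.null(l) || is.null(r)) {
      warning("woman ", w, " excluded: missing ",
              if (is.null(l)) "left" else "right", " view")
      next
    }
    rows[[w]] <- data.frame(id = w, n_clusters_left = l,
                            n_clusters_right = r, mcc_total = l + r)
  }
  cohort <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(id = character(0), n_clusters_left = integer(0),
               n_clusters_right = integer(0), mcc_total = integer(0))
  rownames(cohort) <- NULL
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  if (length(failed) > 0)
    warning(length(failed), " image(s) failed and were skipped")
  invisible(cohort)
}

#' Association analyses on a detected cohort
#'
#' Joins per-woman cluster counts with subject covariates and runs either
#' the adjusted short-term risk model (`mode = "risk"`: case-control
#' logistic regression with `mcc_total` as exposure, plus honest AUCs for
#' the model with and without the cluster-count term) or the age-adjusted
#' risk-factor scan on controls (`mode = "riskfactors"`).
#'
#' @param cohort data.frame or CSV path with `id` and `mcc_total`.
#' @param covariates data.frame or CSV path with `id`, `status` and the
#'   covariate columns.
#' @param mode `"risk"` or `"riskfactors"`.
#' @param config a [mc_config()].
#' @param out_dir optional directory; if given, reports are written as CSV.
#' @return the report: for `"risk"`, list with `model` (a `fit_result`),
#'   `auc_with_mcc`, `auc_without_mcc`; for `"riskfactors"`, the scan
#'   data.frame.
#' @export
associate <- function(cohort, covariates, mode = c("risk", "riskfactors"),
                      config = mc_config(), out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  if (is.character(covariates)) covariates <- utils::read.csv(covariates)
  if (!"id" %in% names(cohort) || !"id" %in% names(covariates))
    stop("join key 'id' must be present in both tables")
  df <- merge(covariates, cohort[, c("id", "mcc_total")], by = "id")
  adj <- c("age_yr", "bmi_kg_m2", "pd_percent", "hrt", "parity", "smoking",
           "diabetes", "age_menopause_yr")
  if (mode == "risk") {
    covs <- c(adj, "mcc_total")
    if (all(df$mcc_total == 0)) {
      warning("all mcc_total are zero; dropping the cluster-count term")
      covs <- adj
    }
    model <- fit_logistic(df, "status", covs)
    auc_with <- if ("mcc_total" %in% covs) {
      honest_auc(df, "status", covs, n_boot = config$stats$n_boot,
                 seed = config$stats$seed)
    } else NULL
    auc_without <- honest_auc(df, "status", adj,
                              n_boot = config$stats$n_boot,
                              seed = config$stats$seed)
    rep <- list(model = model, auc_with_mcc = auc_with,
                auc_without_mcc = auc_without,
                config_hash = attr(config, "config_hash"))
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      tab <- model$table
      tab$config_hash <- attr(config, "config_hash")
      utils::write.csv(tab, file.path(out_dir, "risk_model.csv"),
                       row.names = FALSE)
      auc_tab <- data.frame(
        model = c("with_mcc", "without_mcc"),
        apparent = c(auc_with$apparent_auc %||% NA, auc_without$apparent_auc),
        honest = c(auc_with$honest_auc %||% NA, auc_without$honest_auc),
        config_hash = attr(config, "config_hash"))
      utils::write.csv(auc_tab, file.path(out_dir, "honest_auc.csv"),
                       row.names = FALSE)
    }
    rep
  } else {
    ctl <- df[df$status == "control", , drop = FALSE]
    factors <- c("age_yr", "bmi_kg_m2", "pd_percent", "parity",
                 "age_first_birth_yr", "breastfeeding_months",
                 "breastfeeding", "hrt", "smoking", "diabetes",
                 "age_menopause_yr")
    factors <- intersect(factors, names(ctl))
    scan <- riskfactor_scan(ctl, factors,
                            family_size = config$stats$bonferroni_family)
    scan$config_hash <- attr(config, "config_hash")
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(scan, file.path(out_dir, "riskfactor_scan.csv"),
                       row.names = FALSE)
    }
    scan
  }
}
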