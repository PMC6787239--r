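#' Phantom mammogram specification
#'
#' Describes a synthetic digitised-film mammogram: a half-elliptical breast
#' entering from the left image edge over a dark background, a smooth
#' correlated background texture inside the breast, bright Gaussian specks
#' (microcalcifications, 0.1-1 mm), curvilinear bright ridges (vessels /
#' fibrous strands), bright rectangular film labels outside the breast, and
#' mixed Poisson-Gaussian digitisation noise. The default geometry is
#' 1024 x 768 px at 0.05 mm/px, a desk-scale stand-in for full-resolution
#' film scans.
#'
#' @param shape_px integer (rows, cols), default `c(1024, 768)`.
#' @param spacing_mm pixel spacing (default 0.05).
#' @param background list: `level` (mean breast intensity in counts),
#'   `texture_amplitude` (sd of the smooth texture field), `corr_length_px`
#'   (its correlation length).
#' @param specks data.frame with columns `row`, `col` (0-based px),
#'   `diameter_mm` in `[0.05, 2]`, `amplitude` (counts above background).
#' @param ridges list of ridges, each a list with `points` (n x 2 matrix of
#'   0-based px (row, col) polyline vertices), `width_mm`, `amplitude`.
#' @param labels list of labels, each `list(r0, c0, r1, c1, amplitude)`
#'   (0-based px corners).
#' @param noise list: `poisson_scale` (counts are drawn as
#'   `Poisson(x * s) / s`; larger s = less Poisson noise) and `gaussian_sd`.
#' @param seed integer; fixes the generated image bit-for-bit.
#' @return list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape_px = c(1024, 768), spacing_mm = 0.05,
                         background = list(level = 100, texture_amplitude = 8,
                                           corr_length_px = 30),
                         specks = NULL, ridges = list(), labels = NULL,
                         noise = list(poisson_scale = 1, gaussian_sd = 2),
                         seed = 1) {
  if (is.null(specks)) {
    specks <- data.frame(row = numeric(0), col = numeric(0),
                         diameter_mm = numeric(0), amplitude = numeric(0))
  }
  if (nrow(specks) > 0 &&
      (any(specks$diameter_mm < 0.05) || any(specks$diameter_mm > 2)))
    stop("speck diameters must lie within [0.05, 2] mm")
  if (is.null(labels)) {
    labels <- list(list(r0 = round(shape_px[1] * 0.05),
                        c0 = round(shape_px[2] * 0.86),
                        r1 = round(shape_px[1] * 0.14),
                        c1 = round(shape_px[2] * 0.97), amplitude = 400))
  }
  structure(list(shape_px = as.integer(shape_px), spacing_mm = spacing_mm,
                 background = background, specks = specks, ridges = ridges,
                 labels = labels, noise = noise, seed = as.integer(seed)),
            class = "phantom_spec")
}

# half-ellipse breast entering from the left edge (chest wall at col 0)
phantom_breast_mask <- function(shape_px) {
  nr <- shape_px[1]; nc <- shape_px[2]
  r0 <- nr / 2
  a <- 0.42 * nr; b <- 0.72 * nc
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (( (r - r0) / a)^2 + ((cc - 1) / b)^2 <= 1) * 1L
}

# additive Gaussian bump at 1-based (r, c) with given sigma and amplitude
add_bump <- function(img, r, c, sigma, amplitude) {
  nr <- nrow(img); nc <- ncol(img)
  w <- ceiling(4 * sigma)
  rs <- max(1, round(r) - w):min(nr, round(r) + w)
  cs <- max(1, round(c) - w):min(nc, round(c) + w)
  dr <- outer(rs - r, rep(1, length(cs)))
  dc <- outer(rep(1, length(rs)), cs - c)
  img[rs, cs] <- img[rs, cs] + amplitude * exp(-(dr^2 + dc^2) / (2 * sigma^2))
  img
}

#' Generate a phantom mammogram with ground truth
#'
#' Renders the [phantom_spec()] into a noisy image plus an annotation object
#' holding the true breast mask, speck table and true cluster structure.
#' The true clusters are, by definition, the DBSCAN grouping (5 mm, 3 spots)
#' of the true speck centres -- the same grouping rule the detector uses, so
#' generator and pipeline agree on what a cluster is.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (a [mammogram()]) and `annotation`: list with
#'   `mask` ([breast_mask()]), `specks` (data.frame, 0-based px), `clusters`
#'   (a `cluster_set` over the true speck centres), `n_clusters`,
#'   `cluster_centroids_rc` (matrix, 0-based px).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$shape_px[1]; nc <- spec$shape_px[2]
  mask <- phantom_breast_mask(spec$shape_px)
  bg <- spec$background
  img <- matrix(2, nr, nc)                       # faint film base
  img[mask == 1] <- bg$level
  if (bg$texture_amplitude > 0) {
    field <- matrix(stats::rnorm(nr * nc), nr, nc)
    field <- as.matrix(EBImage::gblur(field, sigma = bg$corr_length_px))
    field <- field / stats::sd(field) * bg$texture_amplitude
    img[mask == 1] <- pmax(img[mask == 1] + field[mask == 1], 1)
  }
  for (lb in spec$labels) {
    rs <- (lb$r0:lb$r1) + 1; cs <- (lb$c0:lb$c1) + 1
    img[rs, cs] <- img[rs, cs] + lb$amplitude
  }
  for (rg in spec$ridges) {
    img <- img + render_ridge(rg, nr, nc, spec$spacing_mm)
  }
  if (nrow(spec$specks) > 0) {
    for (i in seq_len(nrow(spec$specks))) {
      s <- spec$specks[i, ]
      r1b <- s$row + 1; c1b <- s$col + 1
      if (mask[round(r1b), round(c1b)] != 1)
        stop("speck placed outside breast at (", s$row, ", ", s$col, ")")
      sigma <- (s$diameter_mm / spec$spacing_mm) / 4
      img <- add_bump(img, r1b, c1b, sigma, s$amplitude)
    }
  }
  s <- spec$noise$poisson_scale
  if (!is.null(s) && s > 0) {
    img <- matrix(stats::rpois(nr * nc, lambda = pmax(img, 0) * s) / s, nr, nc)
  }
  if (spec$noise$gaussian_sd > 0) {
    img <- img + matrix(stats::rnorm(nr * nc, sd = spec$noise$gaussian_sd),
                        nr, nc)
  }
  img <- pmax(img, 0)
  true_clusters <- dbscan_group(spec$specks, eps_mm = 5, min_pts = 3,
                                spacing_mm = spec$spacing_mm)
  cents <- if (true_clusters$n_clusters > 0) {
    do.call(rbind, lapply(true_clusters$clusters, function(cl) cl$centroid_rc))
  } else {
    matrix(numeric(0), 0, 2)
  }
  list(
    image = mammogram(img, spacing_mm = spec$spacing_mm, bit_depth = 16L),
    annotation = list(mask = breast_mask(mask), specks = spec$specks,
                      clusters = true_clusters,
                      n_clusters = true_clusters$n_clusters,
                      cluster_centroids_rc = cents)
  )
}

# rasterise a polyline ridge: mark dense samples, blur to the stated width,
# renormalise the crest to the stated amplitude
render_ridge <- function(rg, nr, nc, spacing_mm) {
  pts <- rg$points + 1           # to 1-based
  canvas <- matrix(0, nr, nc)
  for (i in seq_len(nrow(pts) - 1)) {
    p <- pts[i, ]; q <- pts[i + 1, ]
    len <- sqrt(sum((q - p)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(len * 2)))
    rs <- round(p[1] + t * (q[1] - p[1]))
    cs <- round(p[2] + t * (q[2] - p[2]))
    ok <- rs >= 1 & rs <= nr & cs >= 1 & cs <= nc
    canvas[cbind(rs[ok], cs[ok])] <- 1
  }
  sigma <- (rg$width_mm / spacing_mm) / 2.355
  out <- as.matrix(EBImage::gblur(canvas, sigma = max(sigma, 0.5)))
  if (max(out) > 0) out <- out / max(out) * rg$amplitude
  out
}

#' Random phantom specification with clustered specks
#'
#' Places `n_clusters` well-separated speck clusters inside the breast (each
#' of `specks_per_cluster` specks within `cluster_radius_mm` of its centre),
#' plus isolated single specks and one curvilinear ridge, and returns the
#' corresponding [phantom_spec()]. Speck amplitude defaults to 6x the
#' background texture sd, the contrast regime the detection pipeline is
#' benchmarked at.
#'
#' @param seed integer seed (drives placement and, via the spec, rendering).
#' @param n_clusters number of true clusters (default 3).
#' @param specks_per_cluster specks per cluster (default 4).
#' @param cluster_radius_mm maximal distance of a speck from its cluster
#'   centre (default 2 mm, so each cluster fits well inside the 5 mm
#'   grouping radius).
#' @param n_isolated isolated specks, placed far from every cluster
#'   (default 2; these must be discarded as DBSCAN noise).
#' @param amplitude speck amplitude in counts. The default 78 is 6x the
#'   effective background standard deviation of the default phantom, which
#'   combines the texture field (sd 8), the Poisson shot noise at the
#'   background level of 100 counts (sd 10) and the Gaussian read noise
#'   (sd 2): `sqrt(64 + 100 + 4) ~ 13`.
#' @param with_ridge include one bright ridge (default TRUE).
#' @param shape_px image shape (default `c(1024, 768)`).
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, n_clusters = 3, specks_per_cluster = 4,
                                cluster_radius_mm = 2, n_isolated = 2,
                                amplitude = 78, with_ridge = TRUE,
                                shape_px = c(1024, 768)) {
  set.seed(seed)
  spacing <- 0.05
  mask <- phantom_breast_mask(shape_px)
  # keep cluster centres >= 3.5 mm inside the breast boundary (including
  # the chest-wall image edge), so that specks scattered up to
  # cluster_radius_mm from the centre stay clear of the detector's 1 mm
  # skin margin
  er <- erode_zero_pad(mask, round(3.5 / spacing))
  inside <- which(er == 1)
  # single specks carry no scatter, so they may sit closer (1.5 mm) to the
  # boundary
  er1 <- erode_zero_pad(mask, round(1.5 / spacing))
  inside1 <- which(er1 == 1)
  nr <- shape_px[1]
  # rejection-sample n points from `pool`: >= self_mm apart from each other
  # and >= exist_mm from every row of `existing`
  pick_far <- function(n, existing, self_mm, exist_mm = self_mm,
                       pool = inside) {
    for (restart in 1:20) {
      out <- matrix(numeric(0), 0, 2)
      tries <- 0
      while (nrow(out) < n && tries < 3000) {
        tries <- tries + 1
        ix <- sample(pool, 1)
        r <- ((ix - 1) %% nr); cc <- ((ix - 1) %/% nr)
        if (nrow(existing) > 0) {
          dmm <- sqrt((existing[, 1] - r)^2 + (existing[, 2] - cc)^2) * spacing
          if (min(dmm) < exist_mm) next
        }
        if (nrow(out) > 0) {
          dmm <- sqrt((out[, 1] - r)^2 + (out[, 2] - cc)^2) * spacing
          if (min(dmm) < self_mm) next
        }
        out <- rbind(out, c(r, cc))
      }
      if (nrow(out) == n) return(out)
    }
    stop("could not place points with required separation")
  }
  none <- matrix(numeric(0), 0, 2)
  # ridge first: a wavy, roughly vertical vessel-like track in the inner
  # third of the breast, jittered a little per seed
  ridges <- list()
  ridge_samples <- none
  if (with_ridge) {
    nc <- shape_px[2]
    rpts <- rbind(
      c(0.28 * nr, 0.10 * nc), c(0.42 * nr, 0.17 * nc),
      c(0.58 * nr, 0.11 * nc), c(0.72 * nr, 0.16 * nc)
    ) + matrix(stats::rnorm(8, sd = 8), 4, 2)
    ridges <- list(list(points = rpts, width_mm = 0.4, amplitude = amplitude))
    # dense samples along the polyline, used as exclusion points
    for (i in 1:(nrow(rpts) - 1)) {
      t <- seq(0, 1, length.out = 20)
      ridge_samples <- rbind(ridge_samples,
                             cbind(rpts[i, 1] + t * (rpts[i + 1, 1] - rpts[i, 1]),
                                   rpts[i, 2] + t * (rpts[i + 1, 2] - rpts[i, 2])))
    }
  }
  # 12 mm separation keeps detected clusters disjoint under the 5 mm
  # grouping radius (2 mm cluster radius each, so > 9 mm suffices)
  centers <- pick_far(n_clusters, ridge_samples, 12, 6)
  specks <- list()
  for (k in seq_len(n_clusters)) {
    placed <- matrix(numeric(0), 0, 2)
    for (j in seq_len(specks_per_cluster)) {
      tries <- 0
      repeat {
        tries <- tries + 1
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0.3, cluster_radius_mm) / spacing
        r <- centers[k, 1] + rad * cos(ang)
        cc <- centers[k, 2] + rad * sin(ang)
        ri <- round(r) + 1; ci <- round(cc) + 1
        if (!(ri >= 1 && ri <= shape_px[1] && ci >= 1 && ci <= shape_px[2] &&
              mask[ri, ci] == 1)) next
        # distinct deposits: >= 1.2 mm apart so specks do not fuse into a
        # single elongated component (relaxed if the cluster is crowded)
        if (nrow(placed) > 0 && tries < 200) {
          dmm <- sqrt((placed[, 1] - r)^2 + (placed[, 2] - cc)^2) * spacing
          if (min(dmm) < 1.2) next
        }
        break
      }
      placed <- rbind(placed, c(r, cc))
      specks[[length(specks) + 1]] <- data.frame(
        row = r, col = cc,
        diameter_mm = stats::runif(1, 0.2, 0.6),
        amplitude = amplitude
      )
    }
  }
  if (n_isolated > 0) {
    # >= 8 mm from cluster centres (so > 5 mm from every cluster speck,
    # which scatter at most 2 mm) and from the ridge; >= 10 mm apart so
    # they stay DBSCAN noise
    iso <- pick_far(n_isolated, rbind(centers, ridge_samples), 10, 8,
                    pool = if (length(inside1) > 0) inside1 else inside)
    for (i in seq_len(n_isolated)) {
      specks[[length(specks) + 1]] <- data.frame(
        row = iso[i, 1], col = iso[i, 2],
        diameter_mm = stats::runif(1, 0.2, 0.6), amplitude = amplitude
      )
    }
  }
  phantom_spec(shape_px = shape_px, specks = do.call(rbind, specks),
               ridges = ridges, seed = seed + 10000L)
}

#' Synthetic case-control cohort specification
#'
#' Defines the generative model for synthetic cohorts: covariate marginals
#' calibrated to the published control characteristics of the CAHRES
#' short-term risk study (postmenopausal Swedish women aged 50-74),
#' per-covariate log-odds effects on case status taken by default from the
#' adjusted risk model of that study, and a hurdle count model for
#' microcalcification clusters with P(>= 1 cluster) = 0.27 at the mean age
#' and a log-odds age effect on cluster presence.
#'
#' @param n_cases,n_controls design sizes (defaults 253 and 728).
#' @param log_or named list of log-odds effects on case status: `age`, `bmi`,
#'   `pd`, `parity`, `hrt_past`, `hrt_current`, `smoking`, `diabetes`,
#'   `age_menopause`, `mcc` (per cluster).
#' @param mcc list: `p_presence` (P(>= 1 cluster) at mean age, default 0.27),
#'   `age_log_or` (log-odds of presence per year of age, default
#'   `log(1.060)`), `lambda_pos` (extra-cluster Poisson mean among women with
#'   clusters, default 0.6).
#' @param marginals named list of covariate marginals; see defaults in the
#'   function body.
#' @param missingness list: `bf` (breastfeeding missing among parous),
#'   `afb` (AFB missing among parous), `duration` (duration missing among
#'   ever-breastfed with known breastfeeding).
#' @param prevalence target population prevalence used to set the logistic
#'   intercept (default 0.02, a rare-disease regime so that generated
#'   control marginals stay at the population calibration targets; at
#'   higher prevalences the controls are visibly depleted of high-risk
#'   covariate values, most noticeably percent density).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 253, n_controls = 728,
                        log_or = list(), mcc = list(), marginals = list(),
                        missingness = list(), prevalence = 0.02, seed = 1) {
  lo <- utils::modifyList(list(
    age = log(0.982), bmi = log(1.069), pd = log(1.022),
    parity = log(0.859), hrt_past = log(0.607), hrt_current = log(2.274),
    smoking = log(1.425), diabetes = log(1.227),
    age_menopause = log(1.007), mcc = log(1.306)
  ), log_or)
  mc <- utils::modifyList(list(p_presence = 0.27, age_log_or = log(1.060),
                               lambda_pos = 0.6), mcc)
  mg <- utils::modifyList(list(
    age_mean = 63.777, age_sd = 6.082,
    bmi_mean = 25.514, bmi_sd = 3.871,
    pd_mean = 14.612, pd_sd = 13.696,
    hrt_probs = c(never = 0.786, past = 0.031, current = 0.183),
    parity_mean = 2.163,
    smoking_ever = 0.404, diabetes_yes = 0.053,
    age_menopause_mean = 50.191, age_menopause_sd = 4.057,
    afb_mean = 24.927, afb_sd = 4.743,
    bf_ever = 0.939,
    bf_months_mean = 11.663, bf_months_sd = 10.341
  ), marginals)
  ms <- utils::modifyList(list(bf = 0.19, afb = 0.05, duration = 0.02),
                          missingness)
  structure(list(n_cases = n_cases, n_controls = n_controls, log_or = lo,
                 mcc = mc, marginals = mg, missingness = ms,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "cohort_spec")
}

# one batch of population subjects (covariates + cluster counts + linear
# predictor without intercept)
draw_population <- function(n, spec) {
  mg <- spec$marginals; lo <- spec$log_or; mc <- spec$mcc
  age <- stats::rnorm(n, mg$age_mean, mg$age_sd)
  bmi <- stats::rnorm(n, mg$bmi_mean, mg$bmi_sd)
  pd_shape <- (mg$pd_mean / mg$pd_sd)^2
  pd <- pmin(stats::rgamma(n, shape = pd_shape,
                           scale = mg$pd_sd^2 / mg$pd_mean), 100)
  hrt <- sample(names(mg$hrt_probs), n, replace = TRUE, prob = mg$hrt_probs)
  parity <- stats::rpois(n, mg$parity_mean)
  smoking <- stats::rbinom(n, 1, mg$smoking_ever)
  diabetes <- stats::rbinom(n, 1, mg$diabetes_yes)
  meno <- stats::rnorm(n, mg$age_menopause_mean, mg$age_menopause_sd)
  p_pres <- stats::plogis(stats::qlogis(mc$p_presence) +
                          mc$age_log_or * (age - mg$age_mean))
  presence <- stats::rbinom(n, 1, p_pres)
  mcc_total <- presence * (1 + stats::rpois(n, mc$lambda_pos))
  lp <- lo$age * (age - mg$age_mean) +
    lo$bmi * (bmi - mg$bmi_mean) +
    lo$pd * (pd - mg$pd_mean) +
    lo$parity * (parity - mg$parity_mean) +
    lo$hrt_past * (hrt == "past") + lo$hrt_current * (hrt == "current") +
    lo$smoking * smoking + lo$diabetes * diabetes +
    lo$age_menopause * (meno - mg$age_menopause_mean) +
    lo$mcc * mcc_total
  data.frame(age_yr = age, bmi_kg_m2 = bmi, pd_percent = pd,
             hrt = hrt, parity = parity,
             smoking = ifelse(smoking == 1, "ever", "never"),
             diabetes = ifelse(diabetes == 1, "yes", "no"),
             age_menopause_yr = meno, mcc_total = mcc_total, lp = lp)
}

#' Generate a synthetic case-control cohort
#'
#' Draws a population from the [cohort_spec()] marginals, assigns case
#' status from a logistic model with the specified log-odds effects (the
#' intercept is solved so the population prevalence matches the spec; under
#' this rare-disease regime the control marginals stay at their calibration
#' targets), and samples exactly `n_cases` cases and `n_controls` controls.
#' Reproductive variables (breastfeeding, duration, age at first birth) are
#' then attached for parous women with the specified missingness rates.
#'
#' @param spec a [cohort_spec()].
#' @return data.frame of subject records: `id`, `status`
#'   (control/case factor), `age_yr`, `bmi_kg_m2`, `pd_percent`, `hrt`,
#'   `parity`, `smoking`, `diabetes`, `age_menopause_yr`, `breastfeeding`,
#'   `breastfeeding_months`, `age_first_birth_yr`, `mcc_total`.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  need_cases <- spec$n_cases; need_controls <- spec$n_controls
  batch_n <- min(max(8000, ceiling(need_cases / spec$prevalence * 1.3)),
                 50000)
  pop <- draw_population(batch_n, spec)
  f <- function(b0) mean(stats::plogis(b0 + pop$lp)) - spec$prevalence
  b0 <- stats::uniroot(f, c(-30, 10))$root
  cases <- list(); controls <- list()
  n_c <- 0L; n_k <- 0L; rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    if (rounds > 40) stop("infeasible prevalence: cannot reach n_cases")
    y <- stats::rbinom(nrow(pop), 1, stats::plogis(b0 + pop$lp))
    if (n_c < need_cases) {
      cases[[rounds]] <- pop[y == 1, , drop = FALSE]
      n_c <- n_c + sum(y == 1)
    }
    if (n_k < need_controls) {
      controls[[rounds]] <- pop[y == 0, , drop = FALSE]
      n_k <- n_k + sum(y == 0)
    }
    if (n_c >= need_cases && n_k >= need_controls) break
    pop <- draw_population(batch_n, spec)
  }
  take <- function(lst, n) {
    df <- do.call(rbind, lst)
    df[seq_len(n), , drop = FALSE]
  }
  out <- rbind(
    if (need_cases > 0) cbind(status = "case", take(cases, need_cases)),
    cbind(status = "control", take(controls, need_controls))
  )
  out$lp <- NULL
  n <- nrow(out)
  mg <- spec$marginals; ms <- spec$missingness
  ip <- which(out$parity > 0)
  bf <- rep(NA_character_, n)
  bf[ip] <- ifelse(stats::rbinom(length(ip), 1, mg$bf_ever) == 1,
                   "ever", "never")
  bf[ip[stats::runif(length(ip)) < ms$bf]] <- NA
  afb <- rep(NA_real_, n)
  afb[ip] <- stats::rnorm(length(ip), mg$afb_mean, mg$afb_sd)
  afb[ip[stats::runif(length(ip)) < ms$afb]] <- NA
  dshape <- (mg$bf_months_mean / mg$bf_months_sd)^2
  dur <- rep(NA_real_, n)
  ie <- which(!is.na(bf) & bf == "ever")
  dur[ie] <- stats::rgamma(length(ie), shape = dshape,
                           scale = mg$bf_months_sd^2 / mg$bf_months_mean)
  dur[ie[stats::runif(length(ie)) < ms$duration]] <- NA
  dur[!is.na(bf) & bf == "never"] <- 0
  out$breastfeeding <- factor(bf, levels = c("never", "ever"))
  out$breastfeeding_months <- dur
  out$age_first_birth_yr <- afb
  out$status <- factor(out$status, levels = c("control", "case"))
  out$hrt <- factor(out$hrt, levels = c("never", "past", "current"))
  out$smoking <- factor(out$smoking, levels = c("never", "ever"))
  out$diabetes <- factor(out$diabetes, levels = c("no", "yes"))
  out <- cbind(id = seq_len(n), out)
  rownames(out) <- NULL
  out
}
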