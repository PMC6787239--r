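# Independent oracles and small fixtures shared across test files.

# Brute-force DBSCAN by direct neighbourhood enumeration. Independent of the
# package implementation: core points from row sums of the distance matrix,
# core clusters from the transitive closure of the core adjacency matrix,
# border points joined to the earliest-seeded cluster (clusters ordered by
# their smallest core index after sorting points by (row, col)), remaining
# points are noise. Returns an assignment vector in the original spot order
# (0 = noise).
brute_dbscan <- function(spots, eps_mm, min_pts, spacing_mm) {
  n <- nrow(spots)
  if (n == 0) return(integer(0))
  ord <- order(spots$row, spots$col)
  pts <- cbind(spots$row, spots$col)[ord, , drop = FALSE] * spacing_mm
  d <- as.matrix(stats::dist(pts))
  nbr <- d <= eps_mm
  core <- rowSums(nbr) >= min_pts
  adj <- nbr & outer(core, core, "&")
  # transitive closure by repeated boolean multiplication
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  assign_sorted <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || assign_sorted[i] != 0L) next
    cl <- cl + 1L
    members <- which(reach[i, ] & core)
    assign_sorted[members] <- cl
  }
  for (i in seq_len(n)) {
    if (core[i] || assign_sorted[i] != 0L) next
    core_nbrs <- which(nbr[i, ] & core)
    if (length(core_nbrs) > 0)
      assign_sorted[i] <- min(assign_sorted[core_nbrs])
  }
  assignment <- integer(n)
  assignment[ord] <- assign_sorted
  assignment
}

# Brute-force Bernoulli likelihood maximisation for y ~ b0 + b1 * x by
# nested grid refinement (no derivatives, no IRLS).
grid_logistic <- function(y, x) {
  nll <- function(b0, b1) {
    p <- stats::plogis(b0 + b1 * x)
    -sum(y * log(p) + (1 - y) * log(1 - p))
  }
  c0 <- c(-5, 5); c1 <- c(-5, 5)
  for (it in 1:40) {
    g0 <- seq(c0[1], c0[2], length.out = 21)
    g1 <- seq(c1[1], c1[2], length.out = 21)
    vals <- outer(g0, g1, Vectorize(nll))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    b0 <- g0[ix[1]]; b1 <- g1[ix[2]]
    w0 <- diff(c0) / 10; w1 <- diff(c1) / 10
    c0 <- c(b0 - w0, b0 + w0); c1 <- c(b1 - w1, b1 + w1)
  }
  c(b0 = b0, b1 = b1)
}

# Greedy one-to-one matching of detected cluster centroids (px) to true
# centroids within tol_mm; returns the number of recovered true clusters.
match_clusters <- function(true_rc, det_rc, tol_mm, spacing_mm = 0.05) {
  if (is.null(det_rc) || nrow(det_rc) == 0 || nrow(true_rc) == 0) return(0L)
  used <- rep(FALSE, nrow(det_rc))
  hits <- 0L
  for (i in seq_len(nrow(true_rc))) {
    d <- sqrt(rowSums((det_rc - matrix(true_rc[i, ], nrow(det_rc), 2,
                                       byrow = TRUE))^2)) * spacing_mm
    d[used] <- Inf
    j <- which.min(d)
    if (is.finite(d[j]) && d[j] <= tol_mm) {
      hits <- hits + 1L
      used[j] <- TRUE
    }
  }
  hits
}

det_centroids <- function(det) {
  do.call(rbind, lapply(det$clusters$clusters, function(cl) cl$centroid_rc))
}

# A quiet small phantom without specks, used by preprocessing tests.
flat_phantom <- function(seed = 1, shape_px = c(256, 192),
                         texture_amplitude = 8, poisson_scale = 0,
                         gaussian_sd = 0) {
  phantom_spec(
    shape_px = shape_px,
    background = list(level = 100, texture_amplitude = texture_amplitude,
                      corr_length_px = 20),
    noise = list(poisson_scale = poisson_scale, gaussian_sd = gaussian_sd),
    seed = seed
  )
}

# A flat full-frame mammogram with Gaussian bumps at the given 0-based
# (row, col) centres; returns list(img, mask covering everything).
bump_image <- function(shape = c(128, 128), centers = NULL, sigma = 2,
                       amplitude = 50, base = 10) {
  px <- matrix(base, shape[1], shape[2])
  if (!is.null(centers)) {
    for (i in seq_len(nrow(centers))) {
      r0 <- centers[i, 1] + 1; c0 <- centers[i, 2] + 1
      rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
      cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
      px <- px + amplitude * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * sigma^2))
    }
  }
  list(img = mammogram(px, spacing_mm = 0.05),
       mask = breast_mask(matrix(1L, shape[1], shape[2])))
}

# Random spot tables for clustering tests.
random_spots <- function(n, extent_px = 200) {
  data.frame(row = stats::runif(n, 0, extent_px),
             col = stats::runif(n, 0, extent_px))
}

adjusted_covariates <- c("age_yr", "bmi_kg_m2", "pd_percent", "hrt",
                         "parity", "smoking", "diabetes",
                         "age_menopause_yr")
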