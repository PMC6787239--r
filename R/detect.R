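#' Hessian-of-Gaussian blob and line responses
#'
#' At scale `sigma_px` the image is Gaussian-smoothed, the second-derivative
#' (Hessian) matrix is formed at every pixel and gamma-normalised (gamma = 2,
#' i.e. multiplied by sigma^2), and its eigenvalues `l1, l2` with
#' `|l1| <= |l2|` are computed in closed form. Bright blobs have two negative
#' eigenvalues of similar magnitude; bright ridges have one strongly negative
#' eigenvalue and one near zero. Two maps are returned:
#' \describe{
#'   \item{blob_map}{`|l2| * exp(-(l1/l2 - 1)^2 / 0.5)` where both
#'     eigenvalues are negative, else 0; the Gaussian factor is maximal when
#'     the eigenvalues are equal (isotropic blob).}
#'   \item{line_map}{`|l2| * exp(-(l1/l2)^2 / line_scale)` where `l2 < 0`,
#'     else 0; a soft realisation of "l1 close to 0, l2 strongly negative"
#'     that stays high along ridge bends, where a hard eigenvalue-ratio
#'     cutoff flickers off.}
#' }
#' Both maps are divided by the same constant (the blob maximum), so a
#' spot's line response is directly comparable with its blob response; the
#' blob map lies in `[0, 1]`, the line map is clipped at 1.
#'
#' @param img an `enhanced_image` (from [dog_filter()]) or matrix.
#' @param sigma_px detection scale in pixels (default 2, mid-band of
#'   microcalcification sizes at 0.05 mm/px).
#' @param line_scale width of the eigenvalue-ratio kernel in the line map
#'   (default 0.5, matching the blob kernel; at a perfect blob,
#'   `l1/l2 = 1`, the line response drops to `exp(-2) ~ 0.14`).
#' @return list with elements `blob_map` and `line_map`, matrices in `[0, 1]`.
#' @export
hessian_response <- function(img, sigma_px = 2, line_scale = 0.5) {
  if (sigma_px <= 0) stop("sigma_px must be positive")
  px <- as_pixels(img)
  g <- as.matrix(EBImage::gblur(px, sigma = sigma_px, boundary = "replicate"))
  d2 <- matrix(c(1, -2, 1), 1, 3)
  lrr <- as.matrix(EBImage::filter2(g, t(d2), boundary = "replicate")) # d2/drow2
  lcc <- as.matrix(EBImage::filter2(g, d2, boundary = "replicate"))    # d2/dcol2
  dxy <- matrix(c(1, 0, -1, 0, 0, 0, -1, 0, 1) / 4, 3, 3)
  lrc <- as.matrix(EBImage::filter2(g, dxy, boundary = "replicate"))
  s2 <- sigma_px^2
  lrr <- s2 * lrr; lcc <- s2 * lcc; lrc <- s2 * lrc
  tr <- lrr + lcc
  disc <- sqrt(pmax((lrr - lcc)^2 + 4 * lrc^2, 0))
  ea <- (tr + disc) / 2
  eb <- (tr - disc) / 2
  # order by magnitude: |l1| <= |l2|
  swap <- abs(ea) > abs(eb)
  l1 <- ifelse(swap, eb, ea)
  l2 <- ifelse(swap, ea, eb)
  blob <- matrix(0, nrow(px), ncol(px))
  sel <- l1 < 0 & l2 < 0
  ratio <- l1[sel] / l2[sel]
  blob[sel] <- abs(l2[sel]) * exp(-(ratio - 1)^2 / 0.5)
  line <- matrix(0, nrow(px), ncol(px))
  lsel <- l2 < 0
  line[lsel] <- abs(l2[lsel]) * exp(-(l1[lsel] / l2[lsel])^2 / line_scale)
  norm <- max(blob)
  if (norm > 0) {
    blob <- blob / norm
    line <- pmin(line / norm, 1)
  }
  list(blob_map = blob, line_map = line)
}

# 8-connected component labeling of a logical/0-1 matrix.
# EBImage::bwlabel is 4-connected, so components are built on the
# 8-neighbour pixel graph instead.
label8 <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  fg <- which(binary != 0)
  lab <- matrix(0L, nr, nc)
  if (length(fg) == 0) return(lab)
  inside <- logical(nr * nc)
  inside[fg] <- TRUE
  edges <- integer(0)
  r <- ((fg - 1L) %% nr) + 1L
  co <- ((fg - 1L) %/% nr) + 1L
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- co + off[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    keep <- inside[nb]
    if (any(keep)) edges <- c(edges, rbind(fg[ok][keep], nb[keep]))
  }
  g <- igraph::make_graph(edges = match(edges, fg), n = length(fg),
                          directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[fg] <- as.integer(comp)
  lab
}

# shape descriptors of one pixel set from second-order moments
spot_moments <- function(rows, cols) {
  n <- length(rows)
  if (n == 1) {
    return(list(ecc = 0, major = 0, minor = 0))
  }
  vr <- stats::var(rows) * (n - 1) / n
  vc <- stats::var(cols) * (n - 1) / n
  cv <- stats::cov(rows, cols) * (n - 1) / n
  tr <- vr + vc
  disc <- sqrt(max((vr - vc)^2 + 4 * cv^2, 0))
  lmax <- (tr + disc) / 2
  lmin <- max((tr - disc) / 2, 0)
  ecc <- if (lmax > 0) sqrt(max(1 - lmin / lmax, 0)) else 0
  list(ecc = ecc, major = 4 * sqrt(lmax), minor = 4 * sqrt(lmin))
}

#' Threshold the blob map into microcalcification candidates
#'
#' Binarises the blob response at an adaptive threshold
#' `mean + k_sigma * sd`, computed over mask pixels with non-zero response,
#' labels connected components with 8-connectivity, and measures one
#' candidate spot per component.
#'
#' @param blob_map matrix in `[0, 1]` from [hessian_response()].
#' @param mask a [breast_mask()].
#' @param k_sigma threshold multiplier (default 3).
#' @param line_map optional line-response matrix; if supplied, each spot's
#'   mean line response is recorded for the later line veto.
#' @param floor smallest normalised blob response treated as non-zero
#'   (default 1e-9); responses below it are numerical round-off from the
#'   FFT-based filtering, not signal.
#' @return data.frame of candidate spots with columns `row`, `col` (centroid,
#'   0-based), `area_px`, `eccentricity`, `major_axis_px`, `minor_axis_px`,
#'   `mean_response`, `blobness`, `mean_line`, and a list column `pixels` of
#'   linear pixel indices.
#' @export
threshold_candidates <- function(blob_map, mask, k_sigma = 3,
                                 line_map = NULL, floor = 1e-9) {
  if (k_sigma <= 0) stop("k_sigma must be positive")
  m <- mask$mask
  if (sum(m) == 0) stop("empty mask")
  vals <- blob_map[m == 1 & blob_map > floor]
  empty <- data.frame(
    row = numeric(0), col = numeric(0), area_px = integer(0),
    eccentricity = numeric(0), major_axis_px = numeric(0),
    minor_axis_px = numeric(0), mean_response = numeric(0),
    blobness = numeric(0), mean_line = numeric(0)
  )
  empty$pixels <- list()
  if (length(vals) == 0) return(empty)
  thr <- mean(vals) + k_sigma * stats::sd(vals)
  if (!is.finite(thr)) thr <- mean(vals)
  thr <- max(thr, floor)
  binary <- (blob_map >= thr) & (m == 1)
  if (!any(binary)) return(empty)
  lab <- label8(binary)
  nr <- nrow(lab)
  fg <- which(lab != 0)
  comp <- split(fg, lab[fg])
  rows <- lapply(comp, function(ix) ((ix - 1L) %% nr) + 1L)
  cols <- lapply(comp, function(ix) ((ix - 1L) %/% nr) + 1L)
  out <- lapply(seq_along(comp), function(i) {
    r <- rows[[i]]; cc <- cols[[i]]
    mom <- spot_moments(r, cc)
    data.frame(
      row = mean(r) - 1, col = mean(cc) - 1,   # 0-based convention
      area_px = length(r),
      eccentricity = mom$ecc,
      major_axis_px = mom$major, minor_axis_px = mom$minor,
      mean_response = mean(blob_map[comp[[i]]]),
      blobness = max(blob_map[comp[[i]]]),
      mean_line = if (is.null(line_map)) NA_real_
                  else mean(line_map[comp[[i]]])
    )
  })
  res <- do.call(rbind, out)
  res$pixels <- comp
  # keep only spots whose (rounded) centroid lies inside the breast mask
  cr <- pmin(pmax(round(res$row) + 1, 1), nrow(m))
  cc <- pmin(pmax(round(res$col) + 1, 1), ncol(m))
  inside <- m[cbind(cr, cc)] == 1
  res <- res[inside, , drop = FALSE]
  rownames(res) <- NULL
  res
}
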