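#' Multilevel Otsu thresholding
#'
#' Generalisation of Otsu's method to three classes: finds the pair of
#' thresholds that maximises the between-class variance of a 256-bin
#' histogram, by exhaustive search over threshold pairs (cheap at 256 bins).
#'
#' @param x numeric vector or matrix of values.
#' @param n_classes number of classes; only 3 is supported.
#' @param n_bins histogram resolution (default 256).
#' @return numeric vector of `n_classes - 1` thresholds on the scale of `x`.
#' @export
otsu_multithreshold <- function(x, n_classes = 3, n_bins = 256) {
  if (n_classes != 3)
    stop("only 3 classes are supported")
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  rng <- range(v)
  if (rng[1] == rng[2]) stop("no foreground found: constant-intensity image")
  # bin midpoints; counts via findInterval
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- pmin(findInterval(v, edges, rightmost.closed = TRUE), n_bins)
  cnt <- tabulate(idx, nbins = n_bins)
  p <- cnt / sum(cnt)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  P <- cumsum(p)                    # class mass up to bin k
  S <- cumsum(p * mids)             # first moment up to bin k
  mu_t <- S[n_bins]
  best <- -Inf; best_k <- c(1L, 2L)
  # classes: [1..k1], (k1..k2], (k2..n_bins]
  for (k1 in 1:(n_bins - 2)) {
    w1 <- P[k1]
    if (w1 == 0) next
    m1 <- S[k1] / w1
    for (k2 in (k1 + 1):(n_bins - 1)) {
      w2 <- P[k2] - P[k1]
      w3 <- 1 - P[k2]
      if (w2 == 0 || w3 == 0) next
      m2 <- (S[k2] - S[k1]) / w2
      m3 <- (mu_t - S[k2]) / w3
      sb <- w1 * (m1 - mu_t)^2 + w2 * (m2 - mu_t)^2 + w3 * (m3 - mu_t)^2
      if (sb > best) { best <- sb; best_k <- c(k1, k2) }
    }
  }
  if (!is.finite(best)) stop("no foreground found: fewer than 3 occupied classes")
  edges[best_k + 1]
}

# neighbour shifts with replicated borders
shift_rep <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  x[ri, ci, drop = FALSE]
}

# grayscale erosion/dilation over the radius-1 disk (3x3 plus/cross);
# EBImage's morphology is binary, so the grayscale version is done with
# min/max over shifted copies
gray_erode_disk1 <- function(x) {
  pmin(x, shift_rep(x, 1, 0), shift_rep(x, -1, 0),
       shift_rep(x, 0, 1), shift_rep(x, 0, -1))
}

gray_dilate_disk1 <- function(x) {
  pmax(x, shift_rep(x, 1, 0), shift_rep(x, -1, 0),
       shift_rep(x, 0, 1), shift_rep(x, 0, -1))
}

# grayscale opening with a disk of one pixel radius: removes bright
# single-pixel dust while preserving larger structures
gray_open_disk1 <- function(x) {
  gray_dilate_disk1(gray_erode_disk1(x))
}

#' Segment the breast profile
#'
#' Separates breast tissue from film labels, tags and background. The image
#' is contrast-enhanced with a logarithmic transform (brightening
#' low-intensity pixels near the skin line), split into three classes by
#' multilevel Otsu thresholding, and the union of the two brightest classes
#' is kept (the darkest class is background). The mask is the largest
#' connected foreground component, smoothed by binary closing then opening
#' with a disk structuring element and hole filling.
#'
#' @param img a [mammogram()].
#' @param smooth_radius_px radius of the disk used for morphological
#'   smoothing of the mask (default 5).
#' @return A [breast_mask()].
#' @export
segment_breast <- function(img, smooth_radius_px = 5) {
  px <- as_pixels(img)
  mx <- max(px)
  if (mx == min(px)) stop("no foreground found: constant-intensity image")
  lg <- log1p(px / mx)
  thr <- otsu_multithreshold(lg, n_classes = 3)
  fg <- (lg > thr[1]) * 1.0   # union of the two brightest classes
  if (sum(fg) == 0) stop("no foreground found")
  fg <- largest_component(fg)
  brush <- EBImage::makeBrush(2 * smooth_radius_px + 1, shape = "disc")
  sm <- EBImage::opening(EBImage::closing(fg, brush), brush)
  sm <- EBImage::fillHull(sm)
  if (sum(sm) == 0) stop("no foreground found after smoothing")
  sm <- largest_component(sm)
  breast_mask(round(as.matrix(sm)))
}

# binary erosion treating everything outside the image as background, so a
# mask region touching the image border is eroded there too (EBImage pads
# with foreground at the border)
erode_zero_pad <- function(m, radius_px) {
  pad <- radius_px + 1
  big <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  er <- as.matrix(EBImage::erode(big, EBImage::makeBrush(2 * radius_px + 1,
                                                         shape = "disc")))
  er[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))]
}

largest_component <- function(binary) {
  lab <- EBImage::bwlabel(binary)
  tab <- tabulate(as.integer(lab))
  (as.matrix(lab) == which.max(tab)) * 1.0
}

#' Forward Anscombe transform
#'
#' `y = 2 * sqrt(x + 3/8)`: approximately converts Poisson noise to
#' unit-variance Gaussian noise, so a Gaussian-noise filter can be applied.
#'
#' @param x non-negative numeric values.
#' @export
anscombe <- function(x) {
  if (any(x < 0)) stop("Anscombe transform requires non-negative intensities")
  2 * sqrt(x + 3 / 8)
}

#' Inverse Anscombe transform
#'
#' Algebraic inverse `x = (y/2)^2 - 3/8`, clipped at zero. The algebraic
#' (rather than exact unbiased) inverse is used: at film intensity levels the
#' bias is negligible and the operation stays closed-form.
#'
#' @param y transformed values.
#' @export
anscombe_inverse <- function(y) {
  pmax((y / 2)^2 - 3 / 8, 0)
}

# local mean/variance via box filtering with replicated borders
local_moments <- function(x, window) {
  box <- matrix(1 / window^2, window, window)
  m <- as.matrix(EBImage::filter2(x, box, boundary = "replicate"))
  v <- as.matrix(EBImage::filter2(x^2, box, boundary = "replicate")) - m^2
  list(mean = m, var = pmax(v, 0))
}

# classic locally adaptive Wiener shrinkage toward the local mean; noise
# variance estimated globally as the mean of local variances inside the mask
wiener_adaptive <- function(x, mask, window) {
  mo <- local_moments(x, window)
  noise <- mean(mo$var[mask == 1])
  gain <- pmax(mo$var - noise, 0) / pmax(mo$var, .Machine$double.eps)
  mo$mean + gain * (x - mo$mean)
}

#' Remove digitisation noise from the breast region
#'
#' Applies, in order: (1) grayscale morphological opening with a disk
#' structuring element of one pixel radius (suppresses dust and single-pixel
#' scanner artefacts); (2) the forward Anscombe transform; (3) a locally
#' adaptive Wiener filter in the Anscombe domain, where the mixed
#' Poisson-Gaussian film noise is approximately stationary Gaussian; (4) the
#' inverse Anscombe transform, clipped at zero. Pixels outside the breast
#' mask are set to zero.
#'
#' @param img a [mammogram()] with non-negative intensities.
#' @param mask a [breast_mask()] on the same grid.
#' @param window odd window size (>= 3) for the adaptive Wiener filter;
#'   default 5.
#' @return A denoised [mammogram()].
#' @export
denoise <- function(img, mask, window = 5) {
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  px <- as_pixels(img)
  m <- mask$mask
  if (!all(dim(px) == dim(m))) stop("mask and image dimensions differ")
  if (any(px < 0)) stop("intensities must be non-negative")
  opened <- gray_open_disk1(px)
  y <- anscombe(pmax(opened, 0))
  yf <- wiener_adaptive(y, m, window)
  out <- anscombe_inverse(yf)
  out[m == 0] <- 0
  mammogram(out, spacing_mm = if (is_mammogram(img)) img$spacing_mm else 0.05,
            bit_depth = if (is_mammogram(img)) img$bit_depth else 16L)
}
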