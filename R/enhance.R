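#' Cosine intensity stretch
#'
#' Spreads out the upper gray levels and contracts the lower ones, so that
#' microcalcifications -- among the brightest objects in the breast -- gain
#' contrast. Intensities are min-max normalised within the breast mask and
#' mapped through `T(x) = 1 - cos(pi * x / 2)`, which is strictly increasing
#' with `T(0) = 0`, `T(1) = 1` and an increasing derivative (compresses low
#' intensities, expands high ones).
#'
#' @param img a [mammogram()].
#' @param mask a [breast_mask()] on the same grid.
#' @return A [mammogram()] with values in `[0, 1]` inside the mask, 0 outside.
#' @export
cosine_stretch <- function(img, mask) {
  px <- as_pixels(img)
  m <- mask$mask
  if (sum(m) == 0) stop("empty mask")
  vals <- px[m == 1]
  lo <- min(vals); hi <- max(vals)
  if (hi == lo) stop("constant intensity within mask; cannot normalise")
  xn <- (px - lo) / (hi - lo)
  xn[xn < 0] <- 0; xn[xn > 1] <- 1
  out <- 1 - cos(pi * xn / 2)
  out[m == 0] <- 0
  mammogram(out, spacing_mm = if (is_mammogram(img)) img$spacing_mm else 0.05,
            bit_depth = if (is_mammogram(img)) img$bit_depth else 16L)
}

#' Difference-of-Gaussians band-pass filter
#'
#' Band-pass filters the image so that objects in the microcalcification
#' size band stand out: the difference of two Gaussian blurs suppresses both
#' fine noise (below `sigma_low_px`) and broad background structure (above
#' `sigma_high_px`). Microcalcifications span roughly 0.1-1.0 mm; at
#' 0.05 mm/pixel that is 2-20 px diameter, motivating the defaults
#' `sigma_low = 1`, `sigma_high = 8`. Negative responses are clipped (bright
#' objects only) and the result is rescaled to `[0, 1]` over the mask.
#'
#' @param img a [mammogram()] (typically the cosine-stretched image).
#' @param sigma_low_px,sigma_high_px Gaussian scales in pixels,
#'   `0 < sigma_low_px < sigma_high_px`.
#' @param mask optional [breast_mask()]; rescaling and zeroing are restricted
#'   to it.
#' @param rescale rescale the clipped response to `[0, 1]` (default TRUE);
#'   set FALSE to obtain the raw band-pass response, e.g. for linearity
#'   checks.
#' @return An object of class `enhanced_image` with fields `pixels` (in
#'   `[0, 1]`), `dog_sigma_low_px`, `dog_sigma_high_px` and `spacing_mm`.
#' @export
dog_filter <- function(img, sigma_low_px = 1, sigma_high_px = 8, mask = NULL,
                       rescale = TRUE) {
  if (!(sigma_low_px > 0 && sigma_high_px > sigma_low_px))
    stop("sigma ordering violated: need 0 < sigma_low_px < sigma_high_px")
  px <- as_pixels(img)
  g1 <- as.matrix(EBImage::gblur(px, sigma = sigma_low_px, boundary = "replicate"))
  g2 <- as.matrix(EBImage::gblur(px, sigma = sigma_high_px, boundary = "replicate"))
  resp <- pmax(g1 - g2, 0)
  if (!is.null(mask)) resp[mask$mask == 0] <- 0
  mx <- max(resp)
  if (rescale && mx > 0) resp <- resp / mx
  structure(
    list(pixels = resp,
         dog_sigma_low_px = sigma_low_px,
         dog_sigma_high_px = sigma_high_px,
         spacing_mm = if (is_mammogram(img)) img$spacing_mm else 0.05),
    class = "enhanced_image"
  )
}

#' @export
print.enhanced_image <- function(x, ...) {
  cat(sprintf("<enhanced_image> %d x %d px, DoG sigmas %.2g/%.2g px\n",
              nrow(x$pixels), ncol(x$pixels),
              x$dog_sigma_low_px, x$dog_sigma_high_px))
  invisible(x)
}
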