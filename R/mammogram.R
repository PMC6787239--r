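#' Construct a mammogram image object
#'
#' Wraps a 2-D matrix of non-negative pixel intensities together with its
#' pixel spacing and bit depth. This is the common currency of the image
#' pipeline; the reference geometry for digitised screen-film mammograms is
#' 4770 x 3580 pixels at 0.05 mm/pixel, but any grid of at least 64 x 64 is
#' accepted (phantoms are typically generated at 1024 x 768).
#'
#' @param pixels numeric matrix (rows x cols) of intensities, all >= 0.
#' @param spacing_mm pixel spacing in mm (default 0.05).
#' @param bit_depth integer bit depth of the source image (default 16).
#' @return An object of class `mammogram` with fields `pixels`, `spacing_mm`
#'   and `bit_depth`.
#' @export
mammogram <- function(pixels, spacing_mm = 0.05, bit_depth = 16L) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (any(!is.finite(pixels))) stop("pixel intensities must be finite")
  if (any(pixels < 0)) stop("pixel intensities must be non-negative")
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop("image dimensions must both be >= 64")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0)
    stop("spacing_mm must be a positive scalar")
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm,
         bit_depth = as.integer(bit_depth)),
    class = "mammogram"
  )
}

#' @export
print.mammogram <- function(x, ...) {
  cat(sprintf("<mammogram> %d x %d px, %.3f mm/px, %d-bit, range [%.3g, %.3g]\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_mammogram <- function(x) inherits(x, "mammogram")

as_pixels <- function(img) {
  if (is.list(img) && !is.null(img$pixels)) img$pixels else as.matrix(img)
}

#' Construct a breast mask
#'
#' @param mask 0/1 matrix marking breast-tissue pixels.
#' @return Object of class `breast_mask` with fields `mask` and `area_px`.
#' @export
breast_mask <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  if (!all(mask %in% c(0L, 1L))) stop("mask must be 0/1-valued")
  area <- sum(mask)
  if (area == 0L) stop("mask has no foreground")
  structure(list(mask = mask, area_px = area), class = "breast_mask")
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask> %d x %d px, area %d px (%.1f%%)\n",
              nrow(x$mask), ncol(x$mask), x$area_px,
              100 * x$area_px / length(x$mask)))
  invisible(x)
}

#' Read a grayscale mammogram from TIFF, PNG or PGM
#'
#' Intensities are returned on the native integer scale of the file
#' (0 .. 2^bit_depth - 1). Only single-channel (grayscale) images are
#' supported; RGB images raise an error.
#'
#' @param path path to an 8- or 16-bit grayscale TIFF, PNG or PGM file.
#' @param spacing_mm pixel spacing in mm; not stored in these formats, so it
#'   must be supplied (default 0.05).
#' @return A [mammogram()] object.
#' @export
read_mammogram <- function(path, spacing_mm = 0.05) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(px)) == 3) {
      if (dim(px)[3] != 1) stop("only grayscale images are supported")
      px <- px[, , 1]
    }
    depth <- if (max(px) > 255) 16L else 8L
  } else if (ext == "png") {
    px <- png::readPNG(path, info = TRUE)
    info <- attr(px, "info")
    depth <- if (!is.null(info$bit.depth)) as.integer(info$bit.depth) else 8L
    if (length(dim(px)) == 3) {
      if (dim(px)[3] != 1) stop("only grayscale images are supported")
      px <- px[, , 1]
    }
    px <- round(px * (2^depth - 1))
    attributes(px) <- list(dim = dim(px))
  } else if (ext == "pgm") {
    pg <- read_pgm(path)
    px <- pg$pixels
    depth <- if (pg$maxval > 255) 16L else 8L
  } else {
    stop("unsupported image format: ", ext)
  }
  mammogram(px, spacing_mm = spacing_mm, bit_depth = depth)
}

# Plain (P2) and raw (P5) PGM reader; maxval <= 65535.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  tokens <- integer(0)
  # header: width, height, maxval, skipping comments
  while (length(tokens) < 3) {
    line <- readLines(con, n = 1)
    line <- sub("#.*$", "", line)
    tokens <- c(tokens, as.integer(strsplit(trimws(line), "\\s+")[[1]]))
    tokens <- tokens[!is.na(tokens)]
  }
  w <- tokens[1]; h <- tokens[2]; maxval <- tokens[3]
  n <- w * h
  if (magic == "P5") {
    sz <- if (maxval > 255) 2L else 1L
    vals <- readBin(con, "integer", n = n, size = sz, signed = FALSE,
                    endian = "big")
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  # PGM is row-major (English reading order)
  list(pixels = matrix(vals, nrow = h, ncol = w, byrow = TRUE),
       maxval = maxval)
}

#' Write a binary mask as an 8-bit PNG (0/255)
#'
#' @param mask a [breast_mask()] or a 0/1 matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "breast_mask")) mask$mask else as.matrix(mask)
  png::writePNG(m * 1.0, target = path)
  invisible(path)
}

#' Write a float image as 32-bit TIFF for inspection
#'
#' @param img a `mammogram`, enhanced image, or numeric matrix with values
#'   in a range writable as float TIFF.
#' @param path output path.
#' @export
write_float_tiff <- function(img, path) {
  px <- as_pixels(img)
  tiff::writeTIFF(px, path, bits.per.sample = 32L)
  invisible(path)
}
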