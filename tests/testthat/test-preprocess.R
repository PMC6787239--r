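test_that("multilevel Otsu splits three well-separated populations", {
  set.seed(1)
  x <- c(rnorm(3000, 10, 1), rnorm(3000, 50, 2), rnorm(3000, 120, 3))
  thr <- otsu_multithreshold(x)
  expect_length(thr, 2)
  # thresholds fall in the gaps between the populations
  expect_gt(thr[1], 13); expect_lt(thr[1], 45)
  expect_gt(thr[2], 55); expect_lt(thr[2], 112)
  expect_error(otsu_multithreshold(rep(5, 100)), "constant")
  expect_error(otsu_multithreshold(x, n_classes = 4), "3 classes")
})

test_that("segment_breast keeps the breast and drops the film label", {
  # bright half-disk entering from the left edge + a small bright label
  nr <- 128; nc <- 128
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  disk <- ((rr - 64)^2 + cc^2) <= 50^2
  px <- matrix(2, nr, nc)
  px[disk] <- 100
  px[10:25, 100:120] <- 200          # label, disjoint from the disk
  m <- segment_breast(mammogram(px))
  expect_s3_class(m, "breast_mask")
  expect_equal(sum(m$mask[10:25, 100:120]), 0)  # label excluded
  inside <- disk & rr > 20 & rr < 108 & cc < 45  # core of the disk
  expect_gt(mean(m$mask[inside]), 0.98)
  expect_error(segment_breast(mammogram(matrix(7, 64, 64))), "no foreground")
})

test_that("segmentation recovers the phantom breast mask under noise", {
  # additive Gaussian noise with sd = 2% of the intensity range
  ph <- make_phantom(flat_phantom(seed = 3, gaussian_sd = 8))
  m <- segment_breast(ph$image)
  truth <- ph$annotation$mask$mask
  dice <- 2 * sum(m$mask & truth) / (sum(m$mask) + sum(truth))
  expect_gte(dice, 0.95)
})

test_that("segmentation is invariant to a constant intensity offset", {
  ph <- make_phantom(flat_phantom(seed = 4, gaussian_sd = 8))
  m1 <- segment_breast(ph$image)
  m2 <- segment_breast(mammogram(ph$image$pixels + 50))
  expect_identical(m1$mask, m2$mask)
})

test_that("mask foreground never touches all four image borders", {
  for (s in 1:5) {
    ph <- make_phantom(flat_phantom(seed = s, gaussian_sd = 4))
    m <- segment_breast(ph$image)$mask
    touches <- c(any(m[1, ] == 1), any(m[nrow(m), ] == 1),
                 any(m[, 1] == 1), any(m[, ncol(m)] == 1))
    expect_lt(sum(touches), 4)
  }
})

test_that("Anscombe transform has the stated closed forms and round-trips", {
  expect_equal(anscombe(0), 2 * sqrt(0.375))
  expect_equal(anscombe(0), 1.2247, tolerance = 1e-4)
  x <- c(0, 0.5, 1, 10, 100, 5000, seq(0, 400, length.out = 997))
  expect_lt(max(abs(anscombe_inverse(anscombe(x)) - x)), 1e-9)
  expect_error(anscombe(-1), "non-negative")
})

test_that("denoise validates inputs and is near-identity on constant regions", {
  ph <- make_phantom(flat_phantom(seed = 5, texture_amplitude = 0))
  mask <- ph$annotation$mask
  expect_error(denoise(ph$image, mask, window = 4), "odd")
  expect_error(denoise(ph$image, mask, window = 1), "odd")
  den <- denoise(ph$image, mask)
  # noiseless piecewise-constant interior: output equals input away from the
  # breast border (opening is identity on flat regions; Wiener shrinks to
  # the local mean, which equals the constant)
  er <- EBImage::erode(mask$mask, EBImage::makeBrush(9, "disc"))
  idx <- which(as.matrix(er) == 1)
  expect_lt(max(abs(den$pixels[idx] - ph$image$pixels[idx])), 1e-6)
  expect_true(all(den$pixels[mask$mask == 0] == 0))
})

test_that("denoising reduces RMSE against the clean image under Poisson noise", {
  clean <- make_phantom(flat_phantom(seed = 6, texture_amplitude = 4))
  noisy_spec <- flat_phantom(seed = 6, texture_amplitude = 4,
                             poisson_scale = 1, gaussian_sd = 2)
  noisy <- make_phantom(noisy_spec)
  mask <- clean$annotation$mask
  den <- denoise(noisy$image, mask)
  idx <- which(mask$mask == 1)
  rmse_in <- sqrt(mean((noisy$image$pixels[idx] - clean$image$pixels[idx])^2))
  rmse_out <- sqrt(mean((den$pixels[idx] - clean$image$pixels[idx])^2))
  expect_lt(rmse_out, rmse_in)
})

test_that("image IO round-trips through PNG, PGM and TIFF", {
  px <- matrix(sample(0:255, 64 * 80, replace = TRUE), 80, 64)
  tmp <- withr::local_tempdir()
  p_png <- file.path(tmp, "img.png")
  png::writePNG(px / 255, p_png)
  expect_equal(read_mammogram(p_png)$pixels, px * 1.0)
  p_pgm <- file.path(tmp, "img.pgm")
  writeLines(c("P2", "64 80", "255",
               paste(as.vector(t(px)), collapse = " ")), p_pgm)
  expect_equal(read_mammogram(p_pgm)$pixels, px * 1.0)
  p_tif <- file.path(tmp, "img.tif")
  tiff::writeTIFF(px / 255, p_tif, bits.per.sample = 8L)
  expect_equal(read_mammogram(p_tif)$pixels, px * 1.0)
  # mask writer emits a valid 0/255 PNG
  m <- matrix(0L, 80, 64); m[20:40, 10:30] <- 1L
  p_mask <- file.path(tmp, "mask.png")
  write_mask_png(breast_mask(m), p_mask)
  back <- png::readPNG(p_mask)
  expect_equal(sort(unique(as.vector(back))), c(0, 1))
  expect_equal(back, m * 1.0, ignore_attr = TRUE)
})
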