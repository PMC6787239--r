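test_that("Hessian eigenvalue maps separate blobs from ridges", {
  nr <- 128; nc <- 128
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  blob <- 50 * exp(-((rr - 40)^2 + (cc - 40)^2) / (2 * 2^2))
  ridge <- 50 * exp(-((cc - 96)^2) / (2 * 2^2))   # vertical bright ridge
  hr <- hessian_response(mammogram(blob + ridge + 10), sigma_px = 2)
  # blob map peaks within 2 px of the blob centre
  ib <- which(hr$blob_map == max(hr$blob_map), arr.ind = TRUE)[1, ]
  expect_lte(max(abs(ib - c(41, 41))), 2)
  # line map peaks on the ridge crest
  il <- which(hr$line_map == max(hr$line_map), arr.ind = TRUE)[1, ]
  expect_lte(abs(il[2] - 97), 2)
  # on the crest (away from the blob) the line response dominates the blob
  # response; at the blob centre the blob response dominates
  expect_gt(hr$line_map[10, 97], hr$blob_map[10, 97])
  expect_gt(hr$blob_map[41, 41], hr$line_map[41, 41])
  expect_error(hessian_response(mammogram(blob + 10), sigma_px = 0), "positive")
})

test_that("thresholding emits one candidate per injected speck", {
  # 10 well-separated specks far above the smooth texture background; no
  # pixel noise, so the adaptive threshold sits on the texture response and
  # each speck yields exactly one component
  ctrs <- cbind(round(seq(250, 774, length.out = 10)),
                round(seq(100, 250, length.out = 10) +
                        c(40, 0, 60, 10, 80, 20, 70, 0, 50, 10)))
  specks <- data.frame(row = ctrs[, 1], col = ctrs[, 2],
                       diameter_mm = 0.4, amplitude = 78)
  spec <- phantom_spec(specks = specks,
                       noise = list(poisson_scale = 0, gaussian_sd = 0),
                       seed = 2)
  ph <- make_phantom(spec)
  mask <- segment_breast(ph$image)
  den <- denoise(ph$image, mask)
  enh <- dog_filter(cosine_stretch(den, mask), 1, 8, mask)
  hr <- hessian_response(enh, sigma_px = 2)
  cand <- threshold_candidates(hr$blob_map, mask, k_sigma = 3)
  expect_equal(nrow(cand), 10)
  for (i in seq_len(10)) {
    d <- sqrt((cand$row - ctrs[i, 1])^2 + (cand$col - ctrs[i, 2])^2)
    expect_lte(min(d), 2)
  }
})

test_that("an all-zero blob map yields no candidates", {
  m <- breast_mask(matrix(1L, 64, 64))
  cand <- threshold_candidates(matrix(0, 64, 64), m, k_sigma = 3)
  expect_equal(nrow(cand), 0)
  expect_error(threshold_candidates(matrix(0, 2, 2),
                                    breast_mask(matrix(0L, 2, 2)), 3),
               "foreground")
})

test_that("adjacent specks merge under 8-connectivity", {
  # two responses 1 px apart diagonally become one component
  bm <- matrix(0, 64, 64)
  bm[30, 30] <- 1; bm[31, 31] <- 1
  bm[10, 10] <- 0.001   # background response so mean + k*sd is below 1
  m <- breast_mask(matrix(1L, 64, 64))
  cand <- threshold_candidates(bm, m, k_sigma = 0.5)
  expect_equal(sum(cand$area_px == 2), 1)
})

test_that("candidate count is non-increasing in k_sigma", {
  ph <- make_phantom(phantom_spec(shape_px = c(512, 384), seed = 21))
  img <- ph$image
  mask <- segment_breast(img)
  den <- denoise(img, mask)
  enh <- dog_filter(cosine_stretch(den, mask), 1, 8, mask)
  hr <- hessian_response(enh, 2)
  counts <- sapply(c(1, 2, 3, 4, 5),
                   function(k) nrow(threshold_candidates(hr$blob_map, mask, k)))
  expect_true(all(diff(counts) <= 0))
})

test_that("candidate centroids always lie inside the breast mask", {
  for (s in 1:3) {
    ph <- make_phantom(random_phantom_spec(s, shape_px = c(1024, 768)))
    img <- ph$image
    mask <- segment_breast(img)
    den <- denoise(img, mask)
    enh <- dog_filter(cosine_stretch(den, mask), 1, 8, mask)
    hr <- hessian_response(enh, 2)
    cand <- threshold_candidates(hr$blob_map, mask, 3)
    if (nrow(cand) > 0) {
      at <- mask$mask[cbind(round(cand$row) + 1, round(cand$col) + 1)]
      expect_true(all(at == 1))
    }
  }
})

test_that("cleaning removes at least half of pure-noise candidates", {
  # phantoms with no injected specks at the reference geometry: everything
  # that survives thresholding is noise, and the cluster module's cleaning
  # (shape/size/line filter, the isolated-spot discard, and the dissolution
  # of diffuse sprawling groups) must remove at least half of it
  drop <- sapply(1:20, function(s) {
    ph <- make_phantom(phantom_spec(seed = s))
    det <- detect_clusters(ph$image)
    kept <- sum(vapply(det$clusters$clusters, function(cl) cl$n_spots,
                       integer(1)))
    1 - kept / max(det$counts$n_candidates, 1)
  })
  expect_gte(median(drop), 0.5)
})
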