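make_spots <- function(rc, area = 5, ecc = 0.3) {
  data.frame(row = rc[, 1], col = rc[, 2],
             area_px = rep_len(area, nrow(rc)),
             eccentricity = rep_len(ecc, nrow(rc)))
}

test_that("shape filter applies the size, shape and line rules", {
  empty <- make_spots(matrix(numeric(0), 0, 2))
  expect_equal(nrow(shape_filter(empty)$spots), 0)
  spots <- data.frame(
    row = c(10, 20, 30, 40), col = c(10, 20, 30, 40),
    area_px = c(1, 5, 200, 8),
    eccentricity = c(0.1, 0.2, 0.3, 0.99),
    mean_line = c(0.1, 0.1, 0.1, 0.1)
  )
  out <- shape_filter(spots, min_area_px = 2, max_area_px = 80,
                      max_eccentricity = 0.95)
  expect_equal(out$spots$row, 20)        # dust, giant and elongated removed
  expect_equal(out$n_removed_area, 2)
  expect_equal(out$n_removed_ecc, 1)
  # line veto on the mean line response
  spots$mean_line <- c(0.1, 0.8, 0.1, 0.1)
  out2 <- shape_filter(spots, line_veto = 0.5)
  expect_equal(out2$n_removed_line, 1)
  expect_error(shape_filter(spots, min_area_px = 10, max_area_px = 5), "<=")
})

test_that("a round-speck phantom survives the filter but a ridge fragment does not", {
  spots <- rbind(
    make_spots(cbind(seq(10, 80, by = 10), seq(10, 80, by = 10))),  # 8 round
    data.frame(row = 90, col = 90, area_px = 40, eccentricity = 0.99)
  )
  spots$mean_line <- c(rep(0.1, 8), 0.9)
  out <- shape_filter(spots)
  expect_equal(nrow(out$spots), 8)
})

test_that("DBSCAN groups by the textbook definitions", {
  # 3 spots pairwise within eps
  s3 <- make_spots(rbind(c(0, 0), c(0, 40), c(40, 0)))   # 2 mm apart at 0.05
  cs <- dbscan_group(s3, eps_mm = 5, min_pts = 3, spacing_mm = 0.05)
  expect_equal(cs$n_clusters, 1)
  expect_equal(cs$n_isolated_discarded, 0)
  expect_equal(cs$clusters[[1]]$n_spots, 3)
  # 2 spots far apart
  s2 <- make_spots(rbind(c(0, 0), c(500, 500)))
  cs2 <- dbscan_group(s2, eps_mm = 5, min_pts = 3, spacing_mm = 0.05)
  expect_equal(cs2$n_clusters, 0)
  expect_equal(cs2$n_isolated_discarded, 2)
  expect_error(dbscan_group(s2, eps_mm = -1, min_pts = 3, 0.05), "positive")
  expect_error(dbscan_group(s2, eps_mm = 5, min_pts = 1, 0.05), ">= 2")
})

test_that("DBSCAN matches a brute-force neighbourhood oracle on random sets", {
  set.seed(99)
  for (i in 1:40) {
    n <- sample(2:12, 1)
    spots <- random_spots(n, extent_px = 300)
    eps <- runif(1, 2, 8)
    mp <- sample(2:4, 1)
    got <- dbscan_group(spots, eps_mm = eps, min_pts = mp,
                        spacing_mm = 0.05)$assignment
    want <- brute_dbscan(spots, eps_mm = eps, min_pts = mp, spacing_mm = 0.05)
    expect_identical(got, want)
  }
})

test_that("clustering is invariant to the order of the input spots", {
  set.seed(7)
  spots <- random_spots(30, extent_px = 400)
  ref <- dbscan_group(spots, 5, 3, 0.05)
  ref_parts <- lapply(ref$clusters, function(cl)
    sort(paste(spots$row[cl$members], spots$col[cl$members])))
  for (i in 1:5) {
    perm <- sample(nrow(spots))
    shuf <- spots[perm, , drop = FALSE]
    cs <- dbscan_group(shuf, 5, 3, 0.05)
    parts <- lapply(cs$clusters, function(cl)
      sort(paste(shuf$row[cl$members], shuf$col[cl$members])))
    expect_setequal(parts, ref_parts)
    expect_equal(cs$n_isolated_discarded, ref$n_isolated_discarded)
  }
})

test_that("cluster count is non-increasing in min_pts", {
  set.seed(13)
  spots <- random_spots(40, extent_px = 300)
  counts <- sapply(2:8, function(mp)
    dbscan_group(spots, 5, mp, 0.05)$n_clusters)
  expect_true(all(diff(counts) <= 0))
})

test_that("per-woman counts add the two sides and demand both views", {
  s0 <- make_spots(matrix(numeric(0), 0, 2))
  cs0 <- dbscan_group(s0, 5, 3, 0.05)
  expect_equal(count_clusters_per_woman(cs0, cs0), 0L)
  s3 <- make_spots(rbind(c(0, 0), c(0, 40), c(40, 0)))
  cs1 <- dbscan_group(s3, 5, 3, 0.05)
  s6 <- make_spots(rbind(c(0, 0), c(0, 40), c(40, 0),
                         c(800, 800), c(800, 840), c(840, 800)))
  cs2 <- dbscan_group(s6, 5, 3, 0.05)
  expect_equal(count_clusters_per_woman(cs2, cs1), 3L)
  expect_error(count_clusters_per_woman(cs1, NULL), "both")
  expect_error(count_clusters_per_woman(cs1, "x"), "cluster_set")
})

test_that("hull areas are positive for non-collinear clusters and 0 otherwise", {
  sq <- make_spots(rbind(c(0, 0), c(0, 40), c(40, 0), c(40, 40)))
  cs <- dbscan_group(sq, 5, 3, 0.05)
  expect_equal(cs$clusters[[1]]$hull_area_mm2, 4)   # (40 px * 0.05)^2
  line <- make_spots(cbind(c(0, 20, 40), c(0, 20, 40)))
  csl <- dbscan_group(line, 5, 3, 0.05)
  expect_equal(csl$clusters[[1]]$hull_area_mm2, 0)
})
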