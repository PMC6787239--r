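#' Mask of long curvilinear bright structures
#'
#' Binarises the line-response map at `level`, labels connected components
#' (8-connectivity) and keeps those whose major axis is at least
#' `min_length_mm`. Individual microcalcifications are at most about 1 mm
#' across, so any contiguous high-line structure longer than 2 mm (the
#' default) is a vessel, fibrous strand or other curvilinear object rather
#' than a single calcification; the kept components are dilated slightly so
#' that bead-like detections sitting on such a structure are caught.
#'
#' @param line_map line-response matrix from [hessian_response()].
#' @param level binarisation level on the normalised line response
#'   (default 0.5).
#' @param min_length_mm minimum major-axis length of a component to count as
#'   a linear structure (default 2 mm).
#' @param spacing_mm pixel spacing.
#' @param grow_px dilation radius applied to the kept components (default 3).
#' @return logical matrix marking pixels on or near long linear structures.
#' @export
linear_structure_mask <- function(line_map, level = 0.5, min_length_mm = 2,
                                  spacing_mm = 0.05, grow_px = 3) {
  vm <- matrix(FALSE, nrow(line_map), ncol(line_map))
  b <- line_map >= level
  if (!any(b)) return(vm)
  lab <- label8(b)
  nr <- nrow(lab)
  fg <- which(lab != 0)
  comp <- split(fg, lab[fg])
  min_len_px <- min_length_mm / spacing_mm
  long <- vapply(comp, function(ix) {
    r <- ((ix - 1L) %% nr) + 1L
    cc <- ((ix - 1L) %/% nr) + 1L
    spot_moments(r, cc)$major >= min_len_px
  }, logical(1))
  if (!any(long)) return(vm)
  vm[unlist(comp[long], use.names = FALSE)] <- TRUE
  as.matrix(EBImage::dilate(vm * 1,
                            EBImage::makeBrush(2 * grow_px + 1,
                                               shape = "disc"))) > 0
}

#' Filter candidate spots by size, shape and line response
#'
#' Realises the cleaning step that removes objects unlike
#' microcalcifications: single-pixel digitisation dust (area below
#' `min_area_px`), objects larger than the microcalcification size band,
#' strongly elongated fragments, and spots lying on curvilinear structures
#' (vessels, fibrous strands). Two line rules act together: a spot whose own
#' mean line response reaches `line_veto` is removed, and so is a spot that
#' touches a long contiguous high-line structure (see
#' [linear_structure_mask()]); noise-driven "beads" along a vessel look
#' compact in isolation and are only caught by the second rule. Beaded
#' arterial calcifications away from a contiguous ridge response pass the
#' per-spot filter -- each bead is compact.
#'
#' @param spots candidate data.frame from [threshold_candidates()].
#' @param min_area_px,max_area_px inclusive area bounds in pixels
#'   (defaults 2 and 80: 0.07-0.45 mm equivalent diameter at 0.05 mm/px).
#' @param max_eccentricity maximum eccentricity (default 0.95).
#' @param line_map optional line-response matrix; spots whose mean line
#'   response is `>= line_veto` are removed. If the spots already carry a
#'   `mean_line` column it is used; otherwise it is computed from `line_map`.
#' @param line_veto veto threshold on the mean line response, also used as
#'   the binarisation level for the linear-structure mask (default 0.5).
#' @param line_length_mm minimum length for the linear-structure veto
#'   (default 2 mm); set to `Inf` to disable it.
#' @param spacing_mm pixel spacing used by the linear-structure veto.
#' @return list with `spots` (surviving rows), and removal counts
#'   `n_removed_area`, `n_removed_ecc`, `n_removed_line`.
#' @export
shape_filter <- function(spots, min_area_px = 2, max_area_px = 80,
                         max_eccentricity = 0.95,
                         line_map = NULL, line_veto = 0.5,
                         line_length_mm = 2, spacing_mm = 0.05) {
  if (min_area_px > max_area_px) stop("min_area_px must be <= max_area_px")
  if (max_eccentricity <= 0 || max_eccentricity > 1)
    stop("max_eccentricity must be in (0, 1]")
  if (nrow(spots) == 0) {
    return(list(spots = spots, n_removed_area = 0L, n_removed_ecc = 0L,
                n_removed_line = 0L))
  }
  mean_line <- spots$mean_line
  if (!is.null(line_map) && (is.null(mean_line) || all(is.na(mean_line)))) {
    mean_line <- vapply(spots$pixels, function(ix) mean(line_map[ix]),
                        numeric(1))
  }
  ok_area <- spots$area_px >= min_area_px & spots$area_px <= max_area_px
  ok_ecc <- spots$eccentricity <= max_eccentricity
  ok_line <- if (is.null(mean_line) || all(is.na(mean_line))) {
    rep(TRUE, nrow(spots))
  } else {
    is.na(mean_line) | mean_line < line_veto
  }
  if (!is.null(line_map) && is.finite(line_length_mm) &&
      !is.null(spots$pixels)) {
    vm <- linear_structure_mask(line_map, level = line_veto,
                                min_length_mm = line_length_mm,
                                spacing_mm = spacing_mm)
    on_line <- vapply(spots$pixels, function(ix) any(vm[ix]), logical(1))
    ok_line <- ok_line & !on_line
  }
  keep <- ok_area & ok_ecc & ok_line
  # removal reasons counted in rule order: area first, then shape, then line
  list(
    spots = {
      s <- spots[keep, , drop = FALSE]; rownames(s) <- NULL; s
    },
    n_removed_area = sum(!ok_area),
    n_removed_ecc = sum(ok_area & !ok_ecc),
    n_removed_line = sum(ok_area & ok_ecc & !ok_line)
  )
}

#' Group spots into clusters with DBSCAN
#'
#' Standard DBSCAN on spot centroids with the Euclidean metric in mm. Points
#' with at least `min_pts` neighbours within `eps_mm` (the point itself
#' included) are core points; clusters are grown from core points; DBSCAN
#' noise points are the discarded isolated spots -- isolated calcifications
#' are not clinically significant. For permutation invariance, spots are
#' sorted by (row, col) before clustering, so border points reachable from
#' several clusters always join the cluster that reaches them first in that
#' deterministic scan order.
#'
#' @param spots data.frame with `row` and `col` centroid columns (pixels).
#' @param eps_mm neighbourhood radius in mm (default 5; with `min_pts = 3`
#'   this encodes the clinical convention of at least 3 calcifications within
#'   about a square centimetre).
#' @param min_pts minimum neighbourhood size for a core point (default 3).
#' @param spacing_mm pixel spacing, used to convert centroids to mm.
#' @param max_hull_mm2 dissolve clusters whose convex hull exceeds this area
#'   (default `Inf`, i.e. plain DBSCAN; the pipeline uses 300 mm^2 = 3 cm^2).
#'   A clinical microcalcification cluster is a compact group within about a
#'   square centimetre; density-chained point sets sprawling over several
#'   cm^2 are a diffuse/scattered pattern, not a cluster, and their spots
#'   are reclassified as discarded noise.
#' @return An object of class `cluster_set`: list with `clusters` (each a
#'   list with `members` -- row indices into `spots` --, `centroid_rc`,
#'   `hull_area_mm2`, `n_spots`), `n_clusters`, `n_isolated_discarded`,
#'   `n_dissolved_diffuse`, `assignment` (integer vector, 0 = noise), and
#'   `n_spots_in`.
#' @export
dbscan_group <- function(spots, eps_mm = 5, min_pts = 3, spacing_mm = 0.05,
                         max_hull_mm2 = Inf) {
  if (eps_mm <= 0) stop("eps_mm must be positive")
  if (min_pts < 2) stop("min_pts must be >= 2")
  n <- nrow(spots)
  if (n == 0) {
    return(structure(list(clusters = list(), n_clusters = 0L,
                          n_isolated_discarded = 0L,
                          n_dissolved_diffuse = 0L,
                          assignment = integer(0), n_spots_in = 0L),
                     class = "cluster_set"))
  }
  ord <- order(spots$row, spots$col)
  pts <- cbind(spots$row, spots$col)[ord, , drop = FALSE] * spacing_mm
  d <- as.matrix(stats::dist(pts))
  nbr <- apply(d <= eps_mm, 1, which, simplify = FALSE)
  if (n == 1) nbr <- list(1L)
  is_core <- vapply(nbr, length, integer(1)) >= min_pts
  assign_sorted <- integer(n)      # 0 = unassigned/noise
  cl_id <- 0L
  for (i in seq_len(n)) {
    if (!is_core[i] || assign_sorted[i] != 0L) next
    cl_id <- cl_id + 1L
    assign_sorted[i] <- cl_id
    queue <- i
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      for (q in nbr[[p]]) {
        if (assign_sorted[q] == 0L) {
          assign_sorted[q] <- cl_id
          if (is_core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  assignment <- integer(n)
  assignment[ord] <- assign_sorted
  clusters <- lapply(seq_len(max(0L, cl_id)), function(k) {
    members <- which(assignment == k)
    r <- spots$row[members]; cc <- spots$col[members]
    list(members = members,
         centroid_rc = c(mean(r), mean(cc)),
         hull_area_mm2 = hull_area(cbind(r, cc) * spacing_mm),
         n_spots = length(members))
  })
  n_dissolved <- 0L
  if (is.finite(max_hull_mm2) && cl_id > 0L) {
    diffuse <- vapply(clusters, function(cl) cl$hull_area_mm2 > max_hull_mm2,
                      logical(1))
    if (any(diffuse)) {
      n_dissolved <- length(unlist(lapply(clusters[diffuse],
                                          `[[`, "members")))
      for (cl in clusters[diffuse]) assignment[cl$members] <- 0L
      clusters <- clusters[!diffuse]
      # renumber the surviving clusters in their original order
      for (k in seq_along(clusters))
        assignment[clusters[[k]]$members] <- k
      cl_id <- length(clusters)
    }
  }
  structure(
    list(clusters = clusters, n_clusters = as.integer(cl_id),
         n_isolated_discarded = sum(assignment == 0L) - n_dissolved,
         n_dissolved_diffuse = n_dissolved,
         assignment = assignment, n_spots_in = n),
    class = "cluster_set"
  )
}

# convex hull area (shoelace); 0 for collinear or < 3 points
hull_area <- function(xy) {
  if (nrow(xy) < 3) return(0)
  h <- grDevices::chull(xy[, 2], xy[, 1])
  if (length(h) < 3) return(0)
  x <- xy[h, 2]; y <- xy[h, 1]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) from %d spot(s); %d isolated discarded\n",
              x$n_clusters, x$n_spots_in, x$n_isolated_discarded))
  invisible(x)
}

#' Total microcalcification cluster count for one woman
#'
#' The per-woman exposure used in the risk models is the total number of
#' clusters over the left and right MLO views; women with a missing side are
#' excluded from the study design, so a missing side is an error here.
#'
#' @param left,right `cluster_set` objects for the left and right breasts.
#' @return integer, `left$n_clusters + right$n_clusters`.
#' @export
count_clusters_per_woman <- function(left, right) {
  if (missing(left) || missing(right) || is.null(left) || is.null(right))
    stop("both left and right cluster sets are required")
  if (!inherits(left, "cluster_set") || !inherits(right, "cluster_set"))
    stop("inputs must be cluster_set objects")
  as.integer(left$n_clusters + right$n_clusters)
}
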