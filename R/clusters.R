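# Cluster extraction on the voxel lattice, spherical ROIs, laterality
# mirroring, per-cycle ROI analyses.

#' Extract connected clusters of significant voxels
#'
#' Connected components of the significant-voxel mask under 26-neighbour
#' lattice connectivity (6-neighbour optional). Cluster size is
#' `count * spacing^3` mm^3; the peak voxel is the member with maximum |r|
#' (ties broken by lowest voxel index).
#'
#' @param x A `swa_perm` or `swa_statmap` object with a voxel grid, or a
#'   tibble of voxel statistics with columns voxel, x, y, z, r.
#' @param mask Logical vector over voxels; defaults to the `significant`
#'   mask of a `swa_perm` input.
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @param spacing_mm Lattice spacing; inferred from the grid when absent.
#' @return Object of class `swa_clusters`: tibble with one row per cluster
#'   (`cluster`, `n_voxels`, `size_mm3`, `peak_voxel`, `peak_r`, `peak_x`,
#'   `peak_y`, `peak_z`) plus a `members` attribute (list of voxel indices).
#' @export
extract_clusters <- function(x, mask = NULL, connectivity = 26,
                             spacing_mm = NULL) {
  if (inherits(x, "swa_perm")) {
    mask <- mask %||% x$significant
    stats <- x$statmap$stats
    spacing_mm <- spacing_mm %||% x$statmap$spacing_mm
  } else if (inherits(x, "swa_statmap")) {
    stats <- x$stats
    spacing_mm <- spacing_mm %||% x$spacing_mm
  } else {
    stats <- as_tibble(x)
  }
  assert_that(!is.null(mask), "a significance mask is required")
  assert_that(all(c("x", "y", "z") %in% names(stats)),
              "voxel coordinates are required for clustering")
  assert_that(length(mask) == nrow(stats), "mask/grid misalignment")
  empty <- tibble(cluster = integer(), n_voxels = integer(),
                  size_mm3 = numeric(), peak_voxel = integer(),
                  peak_r = numeric(), peak_x = numeric(), peak_y = numeric(),
                  peak_z = numeric())
  idx <- which(mask)
  if (length(idx) == 0) {
    return(structure(empty, members = list(), class = c("swa_clusters",
                                                        class(empty))))
  }
  xyz <- as.matrix(stats[idx, c("x", "y", "z")])
  spacing_mm <- spacing_mm %||% infer_spacing(stats) %||% 5
  lim2 <- (spacing_mm * (if (connectivity == 26) sqrt(3) else 1) * 1.001)^2
  d2 <- as.matrix(stats::dist(xyz))^2
  adj <- which(d2 <= lim2 & upper.tri(d2), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(cbind(adj[, 1], adj[, 2]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership

  rows <- lapply(sort(unique(comp)), function(cl) {
    vox <- idx[comp == cl]
    pk <- vox[order(-abs(stats$r[vox]), vox)[1]]
    tibble(cluster = cl, n_voxels = length(vox),
           size_mm3 = length(vox) * spacing_mm^3,
           peak_voxel = stats$voxel[pk], peak_r = stats$r[pk],
           peak_x = stats$x[pk], peak_y = stats$y[pk], peak_z = stats$z[pk])
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$n_voxels))
  out$cluster <- seq_len(nrow(out))
  members <- lapply(sort(unique(comp)), function(cl) idx[comp == cl])
  members <- members[order(-vapply(members, length, integer(1)))]
  structure(out, members = members, class = c("swa_clusters", class(out)))
}

#' Spherical region of interest on the voxel grid
#'
#' Member voxels are all grid points within `radius_mm` (Euclidean, inclusive)
#' of `center`.
#'
#' @param center Length-3 numeric center (mm), typically a cluster's peak
#'   voxel.
#' @param radius_mm Sphere radius in mm (default 15).
#' @param grid Voxel grid tibble with columns voxel, x, y, z.
#' @return Object of class `swa_roi`: list with `center`, `radius_mm`,
#'   `members` (voxel indices), `grid`.
#' @export
build_roi_sphere <- function(center, radius_mm = 15, grid) {
  assert_that(radius_mm >= 0, "radius must be nonnegative")
  d2 <- (grid$x - center[1])^2 + (grid$y - center[2])^2 +
    (grid$z - center[3])^2
  members <- grid$voxel[d2 <= radius_mm^2 + 1e-9]
  if (length(members) == 0) {
    abort("ROI sphere does not intersect the voxel grid")
  }
  structure(list(center = as.numeric(center), radius_mm = radius_mm,
                 members = members, grid = grid),
            class = "swa_roi")
}

#' Mirror an ROI across the sagittal plane
#'
#' Flips the x coordinate of the center (and of every member voxel) to the
#' homologous contralateral region. On an x-symmetric grid the mirrored ROI
#' has identical cardinality and `mirror_roi(mirror_roi(roi))` is the
#' original ROI.
#'
#' @param roi A [build_roi_sphere()] object.
#' @return The mirrored `swa_roi`.
#' @export
mirror_roi <- function(roi) {
  center <- roi$center * c(-1, 1, 1)
  g <- roi$grid
  # map each member to the voxel with mirrored coordinates
  key <- paste(g$x, g$y, g$z)
  mirrored_key <- paste(-g$x[match(roi$members, g$voxel)],
                        g$y[match(roi$members, g$voxel)],
                        g$z[match(roi$members, g$voxel)])
  mem <- g$voxel[match(mirrored_key, key)]
  if (anyNA(mem)) {
    abort("grid is not mirror-symmetric: mirrored voxel(s) missing")
  }
  structure(list(center = center, radius_mm = roi$radius_mm,
                 members = sort(mem), grid = g),
            class = "swa_roi")
}

#' @export
print.swa_roi <- function(x, ...) {
  cat(sprintf("<swa_roi> center (%g, %g, %g) mm, radius %g mm, %d voxels\n",
              x$center[1], x$center[2], x$center[3], x$radius_mm,
              length(x$members)))
  invisible(x)
}

#' Mean map value within an ROI
#'
#' Arithmetic mean of the (normalized, log-transformed) current-density
#' values over the ROI member voxels. For a subject x voxel matrix, one mean
#' per subject.
#'
#' @param map A `swa_map`, a numeric vector of voxel values, or a subject x
#'   voxel matrix.
#' @param roi A [build_roi_sphere()] object.
#' @return Scalar (or per-subject vector) ROI mean.
#' @export
roi_mean_density <- function(map, roi) {
  v <- if (inherits(map, "swa_map")) {
    assert_that(nrow(map$grid) == nrow(roi$grid), "ROI/map grid mismatch")
    map$values
  } else map
  if (is.matrix(v)) {
    assert_that(ncol(v) >= max(roi$members), "ROI exceeds map dimension")
    rowMeans(v[, roi$members, drop = FALSE])
  } else {
    assert_that(length(v) >= max(roi$members), "ROI exceeds map dimension")
    mean(v[roi$members])
  }
}

#' Per-sleep-cycle ROI brain-behavior analysis
#'
#' For each sleep cycle: that cycle's subject x voxel maps are normalized to
#' unit total and log10-transformed, averaged over the ROI, and partially
#' correlated with the behavior controlling for the duration of that specific
#' cycle. Analysis is restricted to the first four cycles; subjects lacking a
#' cycle are excluded listwise (reported). A pooled cycles-2-4 analysis (maps
#' summed before normalization, controlling the summed duration) is appended
#' when at least four cycles are requested.
#'
#' @param cycle_maps List of subject x voxel matrices of nonnegative raw
#'   current-density power, one per cycle (NA rows mark missing cycles).
#' @param behavior Numeric vector, one value per subject.
#' @param durations Subject x cycle matrix of cycle durations (minutes).
#' @param roi A [build_roi_sphere()] object.
#' @param cycles Cycle indices to analyze (default first four).
#' @param pooled Add the pooled cycles-2-4 row (default TRUE).
#' @return Tibble with columns `cycle`, `n`, `r`, `p.value`, `df`,
#'   `r_squared`.
#' @export
per_cycle_analysis <- function(cycle_maps, behavior, durations, roi,
                               cycles = seq_len(min(4, length(cycle_maps))),
                               pooled = TRUE) {
  cycles <- cycles[cycles <= length(cycle_maps)]
  one <- function(raw, dur, label) {
    ok <- which(stats::complete.cases(raw) & is.finite(dur))
    if (length(ok) < 4) {
      warn(sprintf("cycle %s skipped: only %d subjects", label, length(ok)))
      return(NULL)
    }
    m <- raw[ok, , drop = FALSE]
    m <- m / rowSums(m)
    m <- log10(pmax(m, 1e-12))
    res <- partial_correlation(roi_mean_density(m, roi), behavior[ok],
                               covariates = dur[ok])
    tibble(cycle = label, n = length(ok), r = res$r, p.value = res$p.value,
           df = res$df, r_squared = res$r_squared)
  }
  out <- purrr::map(cycles, function(k) {
    one(cycle_maps[[k]], durations[, k], as.character(k))
  })
  if (pooled && length(cycles) >= 4) {
    pool_idx <- intersect(2:4, cycles)
    raw <- Reduce(`+`, cycle_maps[pool_idx])
    out <- c(out, list(one(raw, rowSums(durations[, pool_idx, drop = FALSE]),
                           paste(range(pool_idx), collapse = "-"))))
  }
  dplyr::bind_rows(out)
}
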