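#' Analytic single-sphere EEG lead field on a regular voxel lattice
#'
#' Builds the forward model used throughout the package: a homogeneous
#' conducting sphere (analytic Legendre-series dipole potentials), a cap
#' layout of scalp electrodes, and a regular isotropic voxel lattice strictly
#' inside the head. The gain matrix maps the three Cartesian dipole moment
#' components at every voxel to average-referenced scalp potentials.
#'
#' The lattice is mirror-symmetric about the sagittal plane (x = 0) so that
#' laterality mirroring of regions of interest is exact on the grid.
#'
#' @param n_electrodes Number of scalp electrodes (>= 16). The default 59
#'   mirrors a 64-channel montage after dropping scoring channels.
#' @param n_voxels_per_axis Voxels per axis of the cubic interior lattice.
#' @param spacing_mm Isotropic voxel spacing in mm (default 5).
#' @param head_radius_mm Radius of the spherical head model in mm.
#' @param grid_center_mm Length-3 center of the lattice (mm); the x component
#'   must be 0 to preserve mirror symmetry.
#' @param conductivity Homogeneous conductivity in S/m.
#' @param n_terms Truncation order of the Legendre series.
#'
#' @return An object of class `swa_lead_field`: a list with `gain`
#'   (electrodes x 3*n_voxels, average-reference projected; columns ordered
#'   voxel-major as x,y,z moment components), `electrodes` (tibble x,y,z mm),
#'   `grid` (tibble voxel, x, y, z in mm), `spacing_mm`, `head_radius_mm`,
#'   `conductivity`, `n_terms`.
#' @export
#' @examples
#' lf <- generate_lead_field(n_electrodes = 24, n_voxels_per_axis = 3)
#' dim(lf$gain)
generate_lead_field <- function(n_electrodes = 59,
                                n_voxels_per_axis = 6,
                                spacing_mm = 5,
                                head_radius_mm = 90,
                                grid_center_mm = c(0, 0, 40),
                                conductivity = 0.33,
                                n_terms = 60) {
  assert_that(n_electrodes >= 16, "n_electrodes must be >= 16")
  assert_that(n_voxels_per_axis >= 1 && spacing_mm > 0,
              "invalid lattice parameters")
  assert_that(grid_center_mm[1] == 0,
              "grid_center_mm[1] must be 0 (mirror symmetry about x = 0)")

  elec <- electrode_cap_positions(n_electrodes, head_radius_mm)
  grid <- voxel_lattice(n_voxels_per_axis, spacing_mm, grid_center_mm)
  ecc <- sqrt(grid$x^2 + grid$y^2 + grid$z^2)
  if (any(ecc >= head_radius_mm - spacing_mm / 2)) {
    abort("voxel lattice does not fit strictly inside the head sphere")
  }

  gain <- sphere_gain_matrix(as.matrix(elec[, c("x", "y", "z")]),
                             as.matrix(grid[, c("x", "y", "z")]),
                             head_radius_mm, conductivity, n_terms)
  # average-reference projection: every column sums to zero over electrodes
  gain <- sweep(gain, 2, colMeans(gain))

  structure(
    list(gain = gain, electrodes = elec, grid = grid,
         spacing_mm = spacing_mm, head_radius_mm = head_radius_mm,
         conductivity = conductivity, n_terms = n_terms),
    class = "swa_lead_field"
  )
}

# Deterministic Fibonacci spiral over a spherical cap (theta in [0, cap_deg]).
electrode_cap_positions <- function(n, radius, cap_deg = 100) {
  i <- seq_len(n)
  zmax <- 1
  zmin <- cos(cap_deg * pi / 180)
  z <- zmax - (zmax - zmin) * (i - 0.5) / n
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  r_xy <- sqrt(pmax(0, 1 - z^2))
  tibble(
    channel = sprintf("E%02d", i),
    x = radius * r_xy * cos(phi),
    y = radius * r_xy * sin(phi),
    z = radius * z
  )
}

voxel_lattice <- function(n_per_axis, spacing, center) {
  ax <- (seq_len(n_per_axis) - (n_per_axis + 1) / 2) * spacing
  g <- expand.grid(x = ax + center[1], y = ax + center[2], z = ax + center[3])
  tibble(voxel = seq_len(nrow(g)), x = g$x, y = g$y, z = g$z)
}

# Surface potential of a current dipole in a homogeneous sphere, as gains for
# the three Cartesian unit moments at each source position.
# V_e(q) = (q . bhat) (A_e - x_e B_e) + (q . ehat) B_e with
#   A_e = sum_n c_n n P_n(x_e),  B_e = sum_n c_n P'_n(x_e),
#   c_n = (2n+1)/n * f^(n-1) / R^(n+1) / (4 pi sigma),  x_e = bhat . ehat.
sphere_gain_matrix <- function(elec_pos, src_pos, R, sigma, n_terms) {
  n_e <- nrow(elec_pos)
  n_s <- nrow(src_pos)
  ehat <- unit_rows(elec_pos)
  gain <- matrix(0, n_e, 3 * n_s)
  k0 <- 1 / (4 * pi * sigma)
  n_seq <- seq_len(n_terms)
  for (v in seq_len(n_s)) {
    b <- src_pos[v, ]
    f <- sqrt(sum(b^2))
    if (f < 1e-9) {
      # central dipole: only the n = 1 term survives
      B <- 3 * k0 / R^2
      for (j in 1:3) gain[, 3 * (v - 1) + j] <- B * ehat[, j]
      next
    }
    bhat <- b / f
    x <- as.vector(ehat %*% bhat)
    x <- pmin(1, pmax(-1, x))
    leg <- legendre_table(x, n_terms)
    cn <- k0 * (2 * n_seq + 1) / n_seq * f^(n_seq - 1) / R^(n_seq + 1)
    A <- as.vector(leg$P %*% (cn * n_seq))
    B <- as.vector(leg$dP %*% cn)
    rad <- A - x * B
    for (j in 1:3) {
      gain[, 3 * (v - 1) + j] <- bhat[j] * rad + ehat[, j] * B
    }
  }
  gain
}

#' Scalp potentials for an arbitrary dipole configuration
#'
#' Projects per-voxel dipole moments through a lead field to average-referenced
#' scalp potentials. Mostly a convenience for simulation and tests.
#'
#' @param lead_field A [generate_lead_field()] object.
#' @param moments Numeric vector of length `3 * n_voxels` (voxel-major x,y,z
#'   moment components) or a matrix with that many rows (one column per time
#'   sample).
#' @return Numeric vector (or matrix) of electrode potentials.
#' @export
project_dipoles <- function(lead_field, moments) {
  m <- as.matrix(moments)
  assert_that(nrow(m) == ncol(lead_field$gain),
              "moments must have 3 * n_voxels entries")
  out <- lead_field$gain %*% m
  if (is.vector(moments)) drop(out) else out
}

#' @export
print.swa_lead_field <- function(x, ...) {
  cat(sprintf(
    "<swa_lead_field> %d electrodes, %d voxels @ %g mm (sphere R = %g mm)\n",
    nrow(x$electrodes), nrow(x$grid), x$spacing_mm, x$head_radius_mm))
  invisible(x)
}

#' @export
tidy.swa_lead_field <- function(x, ...) x$grid
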