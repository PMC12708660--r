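# Standardized minimum-norm (sLORETA-style) source localization on the
# spherical-model voxel lattice.

#' Build a standardized minimum-norm inverse operator
#'
#' Computes the regularized minimum-norm transform
#' \eqn{T = K' (K K' + \alpha H)^+} on the average-referenced gain matrix
#' \eqn{K}, with \eqn{H} the average-reference operator and Tikhonov parameter
#' \eqn{\alpha = \mathrm{tr}(K K') / (n_e \cdot \mathrm{snr}^2)}, and the 3x3
#' diagonal blocks of the resolution matrix \eqn{T K} used to standardize
#' voxel estimates (the sLORETA standardization, which gives zero
#' localization error for noiseless single dipoles as snr grows).
#'
#' @param lead_field A [generate_lead_field()] object.
#' @param snr Assumed amplitude signal-to-noise ratio (default 10).
#' @return Object of class `swa_inverse`: list with `transform`
#'   (3*n_voxels x n_electrodes), `res_block_inv` (3 x 3 x n_voxels array of
#'   pseudo-inverted resolution blocks), `alpha`, `snr`, `grid`,
#'   `spacing_mm`.
#' @export
build_inverse_operator <- function(lead_field, snr = 10) {
  assert_that(snr > 0, "snr must be positive")
  K <- lead_field$gain
  n_e <- nrow(K)
  KKt <- tcrossprod(K)
  alpha <- sum(diag(KKt)) / (n_e * snr^2)
  H <- diag(n_e) - matrix(1 / n_e, n_e, n_e)
  M <- pinv_sym(KKt + alpha * H)
  if (max(abs(M)) == 0) abort("gain matrix numerically rank-deficient")
  Tmat <- crossprod(K, M)
  n_v <- nrow(lead_field$grid)
  res_inv <- array(0, c(3, 3, n_v))
  for (v in seq_len(n_v)) {
    rows <- (3 * (v - 1) + 1):(3 * v)
    S <- Tmat[rows, , drop = FALSE] %*% K[, rows, drop = FALSE]
    S <- (S + t(S)) / 2
    res_inv[, , v] <- pinv_sym(S)
  }
  structure(
    list(transform = Tmat, res_block_inv = res_inv, alpha = alpha, snr = snr,
         grid = lead_field$grid, spacing_mm = lead_field$spacing_mm),
    class = "swa_inverse"
  )
}

#' @export
print.swa_inverse <- function(x, ...) {
  cat(sprintf("<swa_inverse> %d voxels, snr = %g, alpha = %.3g\n",
              nrow(x$grid), x$snr, x$alpha))
  invisible(x)
}

#' Standardized voxel map from a single scalp vector
#'
#' Standardized source power for one scalp topography:
#' \eqn{\hat j_v' S_v^{-1} \hat j_v} per voxel.
#'
#' @param inv A [build_inverse_operator()] object.
#' @param scalp Numeric vector of electrode values.
#' @return Numeric vector of standardized voxel powers (>= 0).
#' @export
standardized_map <- function(inv, scalp) {
  assert_that(length(scalp) == ncol(inv$transform),
              "scalp dimension does not match the operator")
  j <- inv$transform %*% (scalp - mean(scalp))
  n_v <- nrow(inv$grid)
  out <- numeric(n_v)
  for (v in seq_len(n_v)) {
    jv <- j[(3 * (v - 1) + 1):(3 * v)]
    out[v] <- drop(crossprod(jv, inv$res_block_inv[, , v] %*% jv))
  }
  out
}

#' Localize band power into voxel space
#'
#' Projects a scalp cross-spectral matrix (accumulated over artifact-free
#' N2/N3 epochs in the SWA band, see [band_cross_spectrum()]) through the
#' standardized inverse: voxel value =
#' \eqn{\mathrm{tr}( S_v^{-1} T_v C T_v' )}, the standardized band
#' current-density power at voxel v.
#'
#' @param x Either a `swa_epochs` object (the cross-spectrum is computed
#'   internally) or a list with element `C` as returned by
#'   [band_cross_spectrum()].
#' @param inv A [build_inverse_operator()] object.
#' @param ... Passed to [band_cross_spectrum()] when `x` is epoched data.
#' @return Object of class `swa_map`: list with `values` (per-voxel
#'   nonnegative power), `normalized`, `log_transformed`, `grid`,
#'   `spacing_mm`, `band`, `n_epochs_used`.
#' @export
localize_band_power <- function(x, inv, ...) {
  if (inherits(x, "swa_epochs")) {
    cs <- band_cross_spectrum(x, ...)
  } else {
    cs <- x
    cs$band <- cs$band %||% c(0.8, 4.6)
    cs$n_epochs_used <- cs$n_epochs_used %||% NA_integer_
  }
  C <- cs$C
  assert_that(ncol(C) == ncol(inv$transform),
              "channel dimension does not match the operator")
  C <- (C + t(C)) / 2
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(abs(C), 1e-300)) {
    abort("accumulated cross-spectrum is not positive semi-definite")
  }
  # average-reference the cross-spectrum (harmless if already referenced)
  C <- sweep(C, 2, colMeans(C))
  C <- sweep(C, 1, rowMeans(C))
  TC <- inv$transform %*% C
  n_v <- nrow(inv$grid)
  vals <- numeric(n_v)
  for (v in seq_len(n_v)) {
    rows <- (3 * (v - 1) + 1):(3 * v)
    B <- TC[rows, , drop = FALSE] %*% t(inv$transform[rows, , drop = FALSE])
    vals[v] <- max(0, sum(diag(inv$res_block_inv[, , v] %*% B)))
  }
  new_swa_map(vals, inv$grid, inv$spacing_mm, band = cs$band,
              n_epochs_used = cs$n_epochs_used)
}

new_swa_map <- function(values, grid, spacing_mm, normalized = FALSE,
                        log_transformed = FALSE, band = c(0.8, 4.6),
                        n_epochs_used = NA_integer_) {
  structure(
    list(values = values, grid = grid, spacing_mm = spacing_mm,
         normalized = normalized, log_transformed = log_transformed,
         band = band, n_epochs_used = n_epochs_used),
    class = "swa_map"
  )
}

#' Normalize a current-density map and log-transform it
#'
#' Divides the voxel values by their sum ("total current density of one",
#' removing global-amplitude confounds without regional specificity), then
#' takes base-10 logarithms with a floor of `eps` applied before the log so
#' the result is finite.
#'
#' @param map A `swa_map` object with nonnegative values.
#' @param log10_transform Apply the log step (default TRUE).
#' @param eps Normalization floor applied before the log.
#' @return The transformed `swa_map` (flags updated).
#' @export
normalize_log_map <- function(map, log10_transform = TRUE, eps = 1e-12) {
  v <- map$values
  assert_that(all(v >= 0), "map values must be nonnegative")
  s <- sum(v)
  if (s <= 0) abort("all-zero map cannot be normalized")
  v <- v / s
  map$normalized <- TRUE
  if (log10_transform) {
    v <- log10(pmax(v, eps))
    map$log_transformed <- TRUE
  }
  map$values <- v
  map
}

#' @export
print.swa_map <- function(x, ...) {
  cat(sprintf("<swa_map> %d voxels%s%s, peak at voxel %d\n",
              length(x$values),
              if (x$normalized) ", normalized" else "",
              if (x$log_transformed) ", log10" else "",
              which.max(x$values)))
  invisible(x)
}

#' @export
tidy.swa_map <- function(x, ...) {
  out <- x$grid
  out$value <- x$values
  out
}
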