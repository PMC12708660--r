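# Recording container, band-pass filtering, bad-channel interpolation,
# average referencing.

#' Construct a sleep EEG recording object
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param rate Sampling rate in Hz.
#' @param channels Character channel labels (default E01..) or a tibble with
#'   columns channel, x, y, z (positions in mm, used for interpolation).
#' @param bad_channels Character vector of bad channel labels.
#' @return Object of class `swa_recording`.
#' @export
new_recording <- function(data, rate, channels = NULL, bad_channels = character()) {
  assert_that(is.matrix(data), "data must be a channels x samples matrix")
  assert_that(rate > 0, "rate must be positive")
  if (is.null(channels)) {
    channels <- sprintf("E%02d", seq_len(nrow(data)))
  }
  if (is.data.frame(channels)) {
    assert_that(nrow(channels) == nrow(data), "channel table/data mismatch")
    pos <- channels
    labels <- channels$channel
  } else {
    assert_that(length(channels) == nrow(data), "channel labels/data mismatch")
    pos <- NULL
    labels <- channels
  }
  structure(
    list(data = data, rate = rate, channels = labels, positions = pos,
         bad_channels = bad_channels),
    class = "swa_recording"
  )
}

#' @export
print.swa_recording <- function(x, ...) {
  cat(sprintf("<swa_recording> %d channels x %d samples @ %g Hz (%.1f min)%s\n",
              nrow(x$data), ncol(x$data), x$rate,
              ncol(x$data) / x$rate / 60,
              if (length(x$bad_channels)) {
                paste0(", bad: ", paste(x$bad_channels, collapse = ","))
              } else ""))
  invisible(x)
}

#' Preprocess a sleep EEG recording
#'
#' Zero-phase band-pass filtering (symmetric FIR applied by FFT convolution
#' with exact group-delay compensation), spherical-spline interpolation of
#' bad channels from the good ones, and re-referencing to the average of all
#' channels (per-sample channel mean becomes ~0).
#'
#' @param rec A [new_recording()] object.
#' @param bad_channels Channel labels to interpolate (defaults to the
#'   recording's own flags).
#' @param band Pass band in Hz (default 0.5-40).
#' @param interp Interpolation method: `"spline"` (spherical spline, order 4,
#'   regularization 1e-5) or `"nearest"` (inverse-angular-distance weighted
#'   mean of the three nearest good electrodes).
#' @param average_reference Apply the common-average reference (default TRUE).
#' @return A preprocessed `swa_recording` (bad channel flags cleared).
#' @export
preprocess_record <- function(rec, bad_channels = rec$bad_channels,
                              band = c(0.5, 40),
                              interp = c("spline", "nearest"),
                              average_reference = TRUE) {
  interp <- match.arg(interp)
  labels <- rec$channels
  bad <- which(labels %in% bad_channels)
  good <- setdiff(seq_along(labels), bad)
  if (length(good) < 2) abort("fewer than 2 good channels: unrecoverable input")
  assert_that(rec$rate >= 100, "sampling rate must be >= 100 Hz")

  h <- design_bandpass_fir(band, rec$rate, n_samples = ncol(rec$data))
  data <- rec$data
  for (ch in good) data[ch, ] <- fft_filt_zerophase(data[ch, ], h)

  if (length(bad) > 0) {
    if (is.null(rec$positions)) {
      abort("bad-channel interpolation requires electrode positions")
    }
    pos <- unit_rows(as.matrix(rec$positions[, c("x", "y", "z")]))
    W <- if (interp == "spline") {
      spherical_spline_weights(pos[good, , drop = FALSE],
                               pos[bad, , drop = FALSE])
    } else {
      nearest_sphere_weights(pos[good, , drop = FALSE],
                             pos[bad, , drop = FALSE])
    }
    data[bad, ] <- W %*% data[good, , drop = FALSE]
  }
  if (average_reference) {
    data <- sweep(data, 2, colMeans(data))
  }
  out <- rec
  out$data <- data
  out$bad_channels <- character()
  out
}

# Linear-phase band-pass FIR (Hamming design). The tap count targets a 0.25 Hz
# transition at the low edge but is capped by the record length so short test
# signals remain filterable.
design_bandpass_fir <- function(band, fs, n_samples,
                                transition_low_hz = 0.25) {
  n <- ceiling(3.3 * fs / transition_low_hz)
  n <- min(n, max(8, floor(n_samples / 3)))
  if (n %% 2 == 1) n <- n + 1  # even order -> type I (odd tap count)
  signal::fir1(n, band / (fs / 2), type = "pass",
               window = signal::hamming(n + 1))
}

# Zero-phase filtering: FFT convolution with a symmetric FIR, output shifted
# by the (ntaps-1)/2 group delay.
fft_filt_zerophase <- function(x, h) {
  nx <- length(x)
  nh <- length(h)
  nfft <- stats::nextn(nx + nh - 1, 2)
  y <- Re(fft(fft(c(x, numeric(nfft - nx))) *
                fft(c(h, numeric(nfft - nh))), inverse = TRUE)) / nfft
  delay <- (nh - 1) / 2
  y[(delay + 1):(delay + nx)]
}

# Magnitude response of an FIR filter at given frequencies.
fir_response <- function(h, f, fs) {
  n <- seq_along(h) - 1
  sapply(f, function(fi) abs(sum(h * exp(-2i * pi * fi * n / fs))))
}

# Perrin-style spherical-spline interpolation operator (order m, Legendre
# series truncation L): rows = bad electrodes, columns = good electrodes.
spherical_spline_weights <- function(good_pos, bad_pos, m = 4, L = 50,
                                     lambda = 1e-5) {
  gfun <- function(cosang) {
    cosang <- pmin(1, pmax(-1, cosang))
    P <- legendre_table(cosang, L)$P
    l <- seq_len(L)
    as.vector(P %*% ((2 * l + 1) / (l * (l + 1))^m)) / (4 * pi)
  }
  ng <- nrow(good_pos)
  G <- matrix(gfun(tcrossprod(good_pos)), ng, ng)
  Gb <- matrix(gfun(bad_pos %*% t(good_pos)), nrow(bad_pos), ng)
  C <- rbind(cbind(G + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  sol <- solve(C)[, seq_len(ng), drop = FALSE]
  cbind(Gb, rep(1, nrow(bad_pos))) %*% sol
}

# Inverse-angular-distance weights over the k nearest good electrodes.
nearest_sphere_weights <- function(good_pos, bad_pos, k = 3) {
  W <- matrix(0, nrow(bad_pos), nrow(good_pos))
  for (i in seq_len(nrow(bad_pos))) {
    ang <- acos(pmin(1, pmax(-1, good_pos %*% bad_pos[i, ])))
    nn <- order(ang)[seq_len(min(k, length(ang)))]
    w <- 1 / pmax(ang[nn], 1e-6)
    W[i, nn] <- w / sum(w)
  }
  W
}
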