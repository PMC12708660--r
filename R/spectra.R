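# Welch spectral estimation and stage-gated SWA spectra.

#' Welch power spectral density
#'
#' One-sided Welch PSD with Hann-windowed segments and 50% overlap
#' (density normalization: integrating the PSD over frequency recovers the
#' signal's mean square power, so a sinusoid of amplitude A integrates to
#' A^2/2 over its spectral peak).
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param seg_sec Segment length in seconds (default 5, i.e. 0.2 Hz bins).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, seg_sec = 5, overlap = 0.5) {
  L <- min(length(x), round(seg_sec * fs))
  step <- max(1, round(L * (1 - overlap)))
  starts <- seq(1, length(x) - L + 1, by = step)
  w <- hann_window(L)
  scale <- 2 / (fs * sum(w^2))
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[1:nf]
    acc <- acc + Mod(X)^2
  }
  psd <- acc * scale / length(starts)
  psd[1] <- psd[1] / 2
  if (L %% 2 == 0) psd[nf] <- psd[nf] / 2
  list(freq = (0:(nf - 1)) * fs / L, psd = psd)
}

# periodic Hann window
hann_window <- function(L) 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)

#' Band power from a Welch PSD
#'
#' Integrates PSD bins whose frequency lies in `[band[1], band[2]]`
#' (inclusive edges) times the bin width.
#'
#' @param x Numeric vector, or the list returned by [welch_psd()].
#' @param fs,seg_sec,overlap As in [welch_psd()] (ignored when `x` is a PSD).
#' @param band Length-2 numeric band edges in Hz.
#' @return Scalar band power (same units as signal variance).
#' @export
band_power <- function(x, fs = NULL, band, seg_sec = 5, overlap = 0.5) {
  p <- if (is.list(x)) x else welch_psd(x, fs, seg_sec, overlap)
  sel <- p$freq >= band[1] & p$freq <= band[2]
  df <- p$freq[2] - p$freq[1]
  sum(p$psd[sel]) * df
}

#' Stage-gated SWA channel spectra
#'
#' Welch spectra (Hann window) of every artifact-free 30-s epoch in the
#' requested sleep stages, averaged over epochs per channel; the SWA band
#' power integrates the 0.8-4.6 Hz bins.
#'
#' @param ep An epoched recording from [epoch_and_mask_artifacts()].
#' @param stages Stages to include (default N2 and N3).
#' @param band SWA band edges in Hz.
#' @param seg_sec,overlap Welch parameters.
#' @return Object of class `swa_spectra`: list with `freq`, `psd`
#'   (channels x frequencies, averaged over epochs), `swa_band_power`
#'   (per channel), `n_epochs_used`, `band`, `channels`.
#' @export
compute_swa_spectra <- function(ep, stages = c("N2", "N3"),
                                band = c(0.8, 4.6),
                                seg_sec = 5, overlap = 0.5) {
  use <- which(ep$epochs$stage %in% stages & !ep$epochs$artifact)
  if (length(use) == 0) {
    abort("no artifact-free epochs in the requested stages")
  }
  nch <- nrow(ep$data)
  first <- welch_psd(get_epoch(ep, use[1])[1, ], ep$rate, seg_sec, overlap)
  psd <- matrix(0, nch, length(first$freq))
  for (i in use) {
    seg <- get_epoch(ep, i)
    for (ch in seq_len(nch)) {
      psd[ch, ] <- psd[ch, ] +
        welch_psd(seg[ch, ], ep$rate, seg_sec, overlap)$psd
    }
  }
  psd <- psd / length(use)
  sel <- first$freq >= band[1] & first$freq <= band[2]
  df <- first$freq[2] - first$freq[1]
  structure(
    list(freq = first$freq, psd = psd,
         swa_band_power = rowSums(psd[, sel, drop = FALSE]) * df,
         n_epochs_used = length(use), band = band,
         channels = ep$channels),
    class = "swa_spectra"
  )
}

#' @export
print.swa_spectra <- function(x, ...) {
  cat(sprintf("<swa_spectra> %d channels, %d epochs, band %.1f-%.1f Hz\n",
              nrow(x$psd), x$n_epochs_used, x$band[1], x$band[2]))
  invisible(x)
}

#' @export
tidy.swa_spectra <- function(x, ...) {
  ch <- x$channels %||% sprintf("E%02d", seq_len(nrow(x$psd)))
  tidyr::expand_grid(channel = ch, freq = x$freq) |>
    dplyr::mutate(psd = as.vector(t(x$psd)))
}

#' Cross-spectral matrix of stage-gated epochs in a frequency band
#'
#' Accumulates the real part of the channel cross-spectrum over Hann-windowed
#' Welch segments of every artifact-free epoch in the requested stages,
#' restricted to frequency bins inside `band`. This is the scalp input to
#' [localize_band_power()].
#'
#' @inheritParams compute_swa_spectra
#' @return List with `C` (channels x channels, PSD-scaled, positive
#'   semi-definite), `n_epochs_used`, `band`.
#' @export
band_cross_spectrum <- function(ep, stages = c("N2", "N3"),
                                band = c(0.8, 4.6),
                                seg_sec = 5, overlap = 0.5) {
  use <- which(ep$epochs$stage %in% stages & !ep$epochs$artifact)
  if (length(use) == 0) {
    abort("no artifact-free epochs in the requested stages")
  }
  nch <- nrow(ep$data)
  L <- min(30 * ep$rate, round(seg_sec * ep$rate))
  step <- max(1, round(L * (1 - overlap)))
  w <- hann_window(L)
  nf <- floor(L / 2) + 1
  freq <- (0:(nf - 1)) * ep$rate / L
  sel <- which(freq >= band[1] & freq <= band[2])
  scale <- 2 / (ep$rate * sum(w^2))
  C <- matrix(0, nch, nch)
  nseg <- 0
  for (i in use) {
    seg <- get_epoch(ep, i)
    starts <- seq(1, ncol(seg) - L + 1, by = step)
    for (s0 in starts) {
      blk <- seg[, s0:(s0 + L - 1), drop = FALSE]
      blk <- (blk - rowMeans(blk)) * rep(w, each = nch)
      X <- t(stats::mvfft(t(blk)))[, sel, drop = FALSE]
      C <- C + Re(X %*% Conj(t(X)))
      nseg <- nseg + 1
    }
  }
  list(C = C * scale / nseg, n_epochs_used = length(use), band = band)
}
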