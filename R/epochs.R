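# 30-s epoching and semi-automatic artifact masking.

#' Epoch a recording by its hypnogram and flag artifact epochs
#'
#' Splits the recording into 30-s epochs labeled by the hypnogram stage. An
#' epoch is flagged artifactual when its channel-mean band power in either the
#' SWA band (0.8-4.6 Hz) or the high band (20-40 Hz) exceeds `factor` times
#' the centered moving average of that band's power over the `window` nearest
#' epochs of the same stage (edge-truncated, the epoch itself included), so
#' that stage-dependent power differences do not masquerade as artifacts.
#'
#' @param rec A (preprocessed) [new_recording()] object.
#' @param hyp A [hypnogram()] object; the recording must cover its span.
#' @param factors Named rejection factors, `swa` and `high`.
#' @param bands List with numeric `swa` and `high` band edges (Hz).
#' @param window Moving-average window in epochs (default 15).
#' @return Object of class `swa_epochs`: the recording data plus an `epochs`
#'   tibble (epoch, stage, artifact, swa_power, high_power, start_sample).
#' @export
epoch_and_mask_artifacts <- function(rec, hyp,
                                     factors = c(swa = 2.0, high = 2.5),
                                     bands = list(swa = c(0.8, 4.6),
                                                  high = c(20, 40)),
                                     window = 15) {
  spe <- hyp$epoch_sec * rec$rate
  assert_that(spe == round(spe), "epoch length must be a whole number of samples")
  n_epochs <- length(hyp$stages)
  if (ncol(rec$data) < n_epochs * spe) {
    abort(sprintf("recording (%d samples) shorter than hypnogram span (%d)",
                  ncol(rec$data), n_epochs * spe))
  }
  pow <- matrix(0, n_epochs, 2)
  for (e in seq_len(n_epochs)) {
    cols <- ((e - 1) * spe + 1):(e * spe)
    sw <- hi <- 0
    for (ch in seq_len(nrow(rec$data))) {
      p <- welch_psd(rec$data[ch, cols], rec$rate)
      sw <- sw + band_power(p, band = bands$swa)
      hi <- hi + band_power(p, band = bands$high)
    }
    pow[e, ] <- c(sw, hi) / nrow(rec$data)
  }
  group <- hyp$stages
  artifact <- rep(FALSE, n_epochs)
  for (b in 1:2) {
    ma <- grouped_moving_average(pow[, b], group, window)
    fac <- factors[[c("swa", "high")[b]]]
    artifact <- artifact | (pow[, b] > fac * ma)
  }
  structure(
    list(data = rec$data[, seq_len(n_epochs * spe), drop = FALSE],
         rate = rec$rate, channels = rec$channels,
         positions = rec$positions, samples_per_epoch = spe,
         epochs = tibble(epoch = seq_len(n_epochs), stage = hyp$stages,
                         group = group, artifact = artifact,
                         swa_power = pow[, 1], high_power = pow[, 2],
                         start_sample = (seq_len(n_epochs) - 1) * spe + 1)),
    class = "swa_epochs"
  )
}

# Centered moving average over the `window` nearest epochs sharing the same
# group label (edge-truncated, self included).
grouped_moving_average <- function(x, group, window) {
  out <- numeric(length(x))
  half <- floor(window / 2)
  for (g in unique(group)) {
    idx <- which(group == g)
    xg <- x[idx]
    n <- length(xg)
    for (j in seq_len(n)) {
      lo <- max(1, j - half)
      hi <- min(n, j + half)
      out[idx[j]] <- mean(xg[lo:hi])
    }
  }
  out
}

#' Extract one epoch's data
#'
#' @param ep A `swa_epochs` object.
#' @param i Epoch index.
#' @return Channels x samples matrix.
#' @export
get_epoch <- function(ep, i) {
  cols <- ep$epochs$start_sample[i] + 0:(ep$samples_per_epoch - 1)
  ep$data[, cols, drop = FALSE]
}

#' @export
print.swa_epochs <- function(x, ...) {
  cat(sprintf("<swa_epochs> %d epochs x %d channels @ %g Hz, %d artifactual\n",
              nrow(x$epochs), nrow(x$data), x$rate, sum(x$epochs$artifact)))
  invisible(x)
}
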