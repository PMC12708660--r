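# Whole-night EEG synthesis: stage-modulated slow oscillations at voxel
# sources projected through the spherical lead field, plus sensor noise.

#' Simulate one subject's whole-night sleep EEG
#'
#' Generates a multichannel night recording from a per-voxel source amplitude
#' profile. Each 30-s epoch contains, at the strongest `n_active` voxels,
#' band-limited oscillatory activity (a sum of sinusoids with random phases
#' drawn over 0.8-4.6 Hz), amplitude-modulated by sleep stage
#' (N3 > N2 >> N1 > REM/W) and by an exponential overnight decline of
#' slow-wave activity, projected to the scalp through the lead field; white
#' sensor noise is added on top, occasionally inflated to emulate movement
#' artifacts.
#'
#' @param profile Numeric vector of per-voxel source amplitudes (one row of
#'   [cohort_source_profiles()]).
#' @param lead_field A [generate_lead_field()] object.
#' @param config A [cohort_config()] object (sensor noise SD, sampling rate,
#'   hypnogram scale, artifact probability).
#' @param seed Integer seed.
#' @param hyp Optional [hypnogram()]; defaults to a seeded
#'   [simulate_hypnogram()] night.
#' @param rate Sampling rate in Hz (defaults to `config$rate`).
#' @param n_active Number of strongest voxels synthesized as active sources.
#' @param n_sinusoids Sinusoids per source per epoch.
#' @param scalp_scale Scalp scaling factor (microvolts per projected source
#'   unit); `NULL` calibrates the cohort-median N3 channel RMS to ~40 uV from
#'   the supplied profile.
#' @param decline_tau_min Time constant (minutes of accumulated sleep) of the
#'   overnight SWA decline.
#' @return List with elements `recording` ([new_recording()]) and `hypnogram`.
#' @export
simulate_sleep_night <- function(profile, lead_field, config, seed,
                                 hyp = NULL, rate = config$rate,
                                 n_active = 16, n_sinusoids = 8,
                                 scalp_scale = NULL,
                                 decline_tau_min = 180) {
  assert_that(length(profile) == nrow(lead_field$grid),
              "profile length must match the voxel grid")
  if (is.null(hyp)) {
    hyp <- simulate_hypnogram(derive_seed(seed, 911),
                              cycle_scale = config$cycle_scale)
  }
  active <- order(profile, decreasing = TRUE)[seq_len(min(n_active,
                                                          length(profile)))]
  active <- active[profile[active] > 0]
  nch <- nrow(lead_field$electrodes)
  spe <- hyp$epoch_sec * rate
  n_epochs <- length(hyp$stages)
  stage_gain <- c(W = 0.04, N1 = 0.15, N2 = 0.5, N3 = 1, REM = 0.06)

  with_seed(seed, {
    # fixed random orientation per active source
    ori <- matrix(rnorm(3 * length(active)), 3)
    ori <- t(t(ori) / sqrt(colSums(ori^2)))
    topo <- sapply(seq_along(active), function(k) {
      v <- active[k]
      lead_field$gain[, (3 * v - 2):(3 * v)] %*% ori[, k]
    })
    if (is.null(scalp_scale)) {
      chan_rms <- sqrt(mean(rowSums(sweep(topo, 2, profile[active], "*")^2)))
      scalp_scale <- 40 / chan_rms
    }
    amps <- profile[active] * scalp_scale

    data <- matrix(0, nch, n_epochs * spe)
    tt <- (0:(spe - 1)) / rate
    sleep_min <- 0
    for (e in seq_len(n_epochs)) {
      st <- hyp$stages[e]
      g <- stage_gain[[st]] * exp(-sleep_min / decline_tau_min)
      if (st != "W") sleep_min <- sleep_min + hyp$epoch_sec / 60
      src <- matrix(0, length(active), spe)
      for (k in seq_along(active)) {
        f <- runif(n_sinusoids, 0.8, 4.6)
        ph <- runif(n_sinusoids, 0, 2 * pi)
        a <- amps[k] * g / sqrt(n_sinusoids / 2)
        src[k, ] <- a * colSums(sin(outer(2 * pi * f, tt) + ph))
      }
      noise_sd <- config$channel_noise_sd *
        if (runif(1) < config$artifact_prob) 8 else 1
      cols <- ((e - 1) * spe + 1):(e * spe)
      data[, cols] <- topo %*% src +
        matrix(rnorm(nch * spe, 0, noise_sd), nch)
    }
    list(
      recording = new_recording(data, rate, channels = lead_field$electrodes),
      hypnogram = hyp
    )
  })
}
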