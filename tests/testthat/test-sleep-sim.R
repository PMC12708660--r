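short_config <- function(n = 4, seed = 1, ...) {
  cohort_config(n_subjects = n, seed = seed, rate = 100, cycle_scale = 0.1,
                artifact_prob = 0, ...)
}

test_that("simulated hypnograms follow the cyclic grammar", {
  h <- simulate_hypnogram(1)
  expect_s3_class(h, "swa_hypnogram")
  expect_gte(nrow(detect_sleep_cycles(h)), 4)
  expect_identical(simulate_hypnogram(5)$stages, simulate_hypnogram(5)$stages)
  # scaled-down nights keep the structure
  hs <- simulate_hypnogram(1, cycle_scale = 0.1)
  expect_gte(nrow(detect_sleep_cycles(hs, nrem_min = 2, rem_min = 1)), 4)
  expect_lt(length(hs$stages), length(h$stages) / 5)
})

test_that("a noiseless single active voxel yields a rank-1 scalp signal", {
  lf <- default_lead_field()
  cfg <- short_config()
  cfg$channel_noise_sd <- 0
  profile <- rep(0, nrow(lf$grid))
  profile[50] <- 1
  hyp <- hypnogram(rep(c("N2", "N3"), 3))
  night <- simulate_sleep_night(profile, lf, cfg, seed = 4, hyp = hyp,
                                n_active = 1, scalp_scale = 1e5)
  sv <- svd(night$recording$data)$d
  expect_lt(sv[2] / sv[1], 1e-8)
})

test_that("identical seeds reproduce the night bit for bit", {
  lf <- default_lead_field()
  cfg <- short_config()
  profile <- rep(1, nrow(lf$grid))
  hyp <- hypnogram(rep("N2", 4))
  n1 <- simulate_sleep_night(profile, lf, cfg, seed = 8, hyp = hyp)
  n2 <- simulate_sleep_night(profile, lf, cfg, seed = 8, hyp = hyp)
  expect_identical(n1$recording$data, n2$recording$data)
})

test_that("N2/N3 epochs carry far more SWA than wake and REM epochs", {
  lf <- default_lead_field()
  cfg <- short_config()
  co <- simulate_cohort(cfg)
  profile <- cohort_source_profiles(co, lf, cfg)[1, ]
  hyp <- hypnogram(c(rep("W", 2), rep("N2", 3), rep("N3", 3),
                     rep("REM", 2)))
  night <- simulate_sleep_night(profile, lf, cfg, seed = 5, hyp = hyp)
  rec <- preprocess_record(night$recording)
  ep <- epoch_and_mask_artifacts(rec, hyp, factors = c(swa = 50, high = 50))
  deep <- compute_swa_spectra(ep)$swa_band_power
  wake <- compute_swa_spectra(ep, stages = c("W", "REM"))$swa_band_power
  expect_gt(mean(deep), 20 * mean(wake))
})

test_that("the full EEG pipeline sees SWA grow with the planted source amplitude", {
  # two paired nights differing only in the effect-voxel amplitude
  lf <- default_lead_field()
  cfg <- short_config()
  co <- simulate_cohort(cfg)
  profile <- cohort_source_profiles(co, lf, cfg)[1, ]
  eff <- swabias:::resolve_effect_voxel(lf$grid, cfg)
  prof2 <- profile
  prof2[eff] <- 2 * prof2[eff]
  inv <- default_inverse(snr = 10)
  value_at <- function(p) {
    night <- simulate_sleep_night(p, lf, cfg, seed = 21, scalp_scale = 2e5,
                                  hyp = simulate_hypnogram(3,
                                                           cycle_scale = 0.1))
    rec <- preprocess_record(night$recording)
    ep <- epoch_and_mask_artifacts(rec, night$hypnogram)
    localize_band_power(ep, inv)$values[eff]
  }
  expect_gt(value_at(prof2), value_at(profile))
})

test_that("the full EEG pipeline recovers a planted across-subject gradient", {
  # deterministic amplitude gradient at the effect voxel across 8 nights;
  # the localized, normalized, log-transformed SWA at that voxel must track it
  lf <- default_lead_field()
  cfg <- short_config(n = 8)
  cfg$cycle_scale <- 0.06
  co <- simulate_cohort(cfg)
  profiles <- cohort_source_profiles(co, lf, cfg)
  eff <- swabias:::resolve_effect_voxel(lf$grid, cfg)
  amps <- seq(0.3, 3, length.out = 8)
  inv <- default_inverse(snr = 10)
  vals <- vapply(1:8, function(i) {
    p <- profiles[i, ]
    p[eff] <- amps[i]
    night <- simulate_sleep_night(p, lf, cfg, seed = 100 + i,
                                  scalp_scale = 2e5)
    rec <- preprocess_record(night$recording)
    ep <- epoch_and_mask_artifacts(rec, night$hypnogram)
    m <- normalize_log_map(localize_band_power(ep, inv))
    m$values[eff]
  }, 0)
  expect_gt(cor(vals, amps), 0.7)
})
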