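test_that("zero scalp data gives an all-zero standardized map", {
  inv <- default_inverse(snr = 10)
  expect_equal(standardized_map(inv, rep(0, 59)), rep(0, 216))
  m <- localize_band_power(list(C = matrix(0, 59, 59)), inv)
  expect_equal(m$values, rep(0, 216))
  expect_error(normalize_log_map(m), "all-zero")
})

test_that("noiseless single dipoles localize with zero error at high snr", {
  lf <- default_lead_field()
  inv <- default_inverse(snr = 1e6)
  set.seed(3)
  for (i in 1:20) {
    v <- sample(nrow(lf$grid), 1)
    q <- rnorm(3)
    scalp <- drop(lf$gain[, (3 * v - 2):(3 * v)] %*% q)
    expect_equal(which.max(standardized_map(inv, scalp)), v)
  }
})

test_that("standardized maps are invariant to joint gain/data scaling", {
  lf <- default_lead_field()
  inv <- build_inverse_operator(lf, snr = 10)
  v <- 101
  scalp <- drop(lf$gain[, (3 * v - 2):(3 * v)] %*% c(0.3, -1, 0.5))
  m1 <- standardized_map(inv, scalp)
  lf2 <- lf
  lf2$gain <- 5 * lf$gain
  m2 <- standardized_map(build_inverse_operator(lf2, snr = 10), 5 * scalp)
  expect_equal(m1, m2, tolerance = 1e-10)
})

test_that("maps are reference-invariant and quadratic in the recording scale", {
  lf <- default_lead_field()
  inv <- default_inverse(snr = 10)
  v <- 40
  scalp <- drop(lf$gain[, (3 * v - 2):(3 * v)] %*% c(1, 1, -2))
  m0 <- localize_band_power(list(C = tcrossprod(scalp)), inv)
  # common offset on all channels changes nothing (average reference)
  m_off <- localize_band_power(list(C = tcrossprod(scalp + 3)), inv)
  expect_equal(m0$values, m_off$values, tolerance = 1e-5)
  # multiplying the EEG by 3 scales power maps by 9 ...
  m3 <- localize_band_power(list(C = tcrossprod(3 * scalp)), inv)
  expect_equal(m3$values, 9 * m0$values, tolerance = 1e-9)
  # ... and relative maps are unchanged (tested at 0.1x, 1x, 10x)
  for (s in c(0.1, 10)) {
    ms <- localize_band_power(list(C = tcrossprod(s * scalp)), inv)
    expect_equal(normalize_log_map(ms)$values,
                 normalize_log_map(m0)$values, tolerance = 1e-9)
  }
})

test_that("normalization and log transform match the hand example", {
  grid <- tibble::tibble(voxel = 1:4, x = c(0, 5, 0, 5), y = 0,
                         z = c(0, 0, 5, 5))
  m <- swabias:::new_swa_map(c(2, 2, 4, 8), grid, 5)
  nm <- normalize_log_map(m, log10_transform = FALSE)
  expect_equal(nm$values, c(0.125, 0.125, 0.25, 0.5))
  expect_equal(sum(nm$values), 1, tolerance = 1e-12)
  lm_ <- normalize_log_map(m)
  expect_equal(lm_$values, log10(c(0.125, 0.125, 0.25, 0.5)),
               tolerance = 1e-12)
  expect_equal(round(lm_$values, 3), c(-0.903, -0.903, -0.602, -0.301))
  # uniform map over V voxels -> every log value is log10(1/V)
  u <- normalize_log_map(swabias:::new_swa_map(rep(7, 4), grid, 5))
  expect_equal(u$values, rep(log10(1 / 4), 4), tolerance = 1e-12)
})

test_that("a simulated band-limited source is recovered through the csd path", {
  lf <- default_lead_field()
  inv <- default_inverse(snr = 1e6)
  v <- 151
  fs <- 100
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  src <- 30 * sin(2 * pi * 2.2 * t) + 20 * sin(2 * pi * 3.6 * t + 1)
  q <- c(0.2, 0.7, -0.4)
  data <- outer(drop(lf$gain[, (3 * v - 2):(3 * v)] %*% q), c(src, src))
  rec <- new_recording(data, fs, channels = lf$electrodes)
  ep <- epoch_and_mask_artifacts(rec, hypnogram(rep("N2", 2)),
                                 factors = c(swa = 100, high = 100))
  m <- localize_band_power(ep, inv)
  expect_equal(which.max(m$values), v)
  expect_true(all(m$values >= 0))
})

test_that("a non-PSD cross-spectrum is rejected", {
  inv <- default_inverse(snr = 10)
  C <- diag(59)
  C[1, 1] <- -1
  expect_error(localize_band_power(list(C = C), inv), "positive semi-definite")
})
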