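test_that("hypnogram validates its stage vocabulary and lights markers", {
  expect_error(hypnogram(c("N2", "N4", "W")), "N4")
  expect_error(hypnogram(c("N2", "W"), lights_off_epoch = 2,
                         lights_on_epoch = 2), "lights")
  h <- hypnogram(c("W", "N2", "REM"))
  expect_equal(h$lights_on_epoch, 3L)
})

test_that("architecture matches the hand-worked nine-epoch example", {
  h <- hypnogram(c("W", "W", "N1", "N2", "N3", "N3", "REM", "W", "N2"))
  a <- sleep_architecture(h)
  expect_equal(a$tst_min, 3.0)
  expect_equal(a$waso_min, 0.5)
  expect_equal(a$sleep_efficiency_pct, 100 * 3 / 4.5, tolerance = 1e-12)
  expect_equal(a$sleep_latency_min, 1.0)
  expect_equal(a$pct_n1 + a$pct_n2 + a$pct_n3 + a$pct_rem, 100,
               tolerance = 1e-9)
})

test_that("an all-N2 night spanning the lights interval is 100% efficient", {
  a <- sleep_architecture(hypnogram(rep("N2", 20)))
  expect_equal(a$sleep_efficiency_pct, 100)
  expect_equal(a$waso_min, 0)
  expect_error(sleep_architecture(hypnogram(rep("W", 5))), "no sleep")
})

test_that("stage percentages always close to exactly 100", {
  for (s in 1:5) {
    h <- simulate_hypnogram(s)
    a <- sleep_architecture(h)
    expect_equal(a$pct_n1 + a$pct_n2 + a$pct_n3 + a$pct_rem, 100,
                 tolerance = 1e-9)
  }
})

test_that("cycle detection reproduces the two-cycle hand example", {
  h <- hypnogram(c(rep("N2", 40), rep("REM", 12), rep("N2", 60),
                   rep("REM", 20)))
  cyc <- detect_sleep_cycles(h)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$start_epoch, c(1, 53))
  expect_equal(cyc$end_epoch, c(52, 132))
  expect_equal(cyc$nrem_minutes, c(20, 30))
  expect_equal(cyc$rem_minutes, c(6, 10))
})

test_that("cycle edge rules: all wake, trailing NREM, short-REM absorption, first-REM exemption", {
  expect_equal(nrow(detect_sleep_cycles(hypnogram(rep("W", 30)))), 0)
  # trailing NREM without REM closes the last cycle at the final sleep epoch
  h <- hypnogram(c(rep("N2", 40), rep("REM", 12), rep("N3", 50), "W", "W"))
  cyc <- detect_sleep_cycles(h)
  expect_equal(nrow(cyc), 2)
  expect_equal(cyc$end_epoch[2], 102)
  expect_equal(cyc$rem_minutes[2], 0)
  # the first REM period is exempt from the minimum, later short ones are not
  h2 <- hypnogram(c(rep("N2", 40), rep("REM", 4), rep("N2", 40),
                    rep("REM", 4), rep("N2", 40), rep("REM", 12)))
  cyc2 <- detect_sleep_cycles(h2)
  expect_equal(nrow(cyc2), 2)
  expect_equal(cyc2$end_epoch[1], 44)   # 4-epoch REM accepted only as first
  expect_equal(cyc2$rem_minutes[2], 2 + 6)  # short bout absorbed into cycle 2
})

test_that("detected cycles are disjoint, ordered, and bounded by TST", {
  for (s in c(2, 8)) {
    h <- simulate_hypnogram(s)
    cyc <- detect_sleep_cycles(h)
    expect_gte(nrow(cyc), 4)
    expect_true(all(diff(cyc$start_epoch) > 0))
    expect_true(all(cyc$end_epoch >= cyc$start_epoch))
    expect_true(all(head(cyc$end_epoch, -1) < tail(cyc$start_epoch, -1)))
    expect_lte(sum(cyc$nrem_minutes + cyc$rem_minutes),
               sleep_architecture(h)$tst_min)
  }
})

test_that("epoch_cycle_index maps epochs onto their cycles", {
  h <- hypnogram(c(rep("N2", 40), rep("REM", 12), rep("N2", 60),
                   rep("REM", 20)))
  idx <- epoch_cycle_index(h, detect_sleep_cycles(h))
  expect_equal(idx[1], 1L)
  expect_equal(idx[52], 1L)
  expect_equal(idx[53], 2L)
  expect_equal(idx[132], 2L)
})
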