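test_that("cohort config validates its invariants", {
  expect_error(cohort_config(n_subjects = 3), ">= 4")
  expect_error(cohort_config(r_true = 1.2), "r_true")
  expect_error(cohort_config(behavior_sd = 0), "positive")
})

test_that("planted amplitude-behavior correlation converges to r_true", {
  co <- simulate_cohort(cohort_config(n_subjects = 2000, r_true = 0.5,
                                      seed = 10))
  expect_lt(abs(cor(co$source_amp, co$behavior) - 0.5), 0.05)
  co0 <- simulate_cohort(cohort_config(n_subjects = 2000, r_true = 0,
                                       seed = 11))
  expect_lt(abs(cor(co0$source_amp, co0$behavior)), 0.1)
})

test_that("cohort draws are seeded and reproducible", {
  cfg <- cohort_config(n_subjects = 12, seed = 99)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cm1 <- simulate_current_density_cohort(cfg)
  cm2 <- simulate_current_density_cohort(cfg)
  expect_identical(cm1$maps, cm2$maps)
})

test_that("current-density maps are nonnegative and sum to one per subject", {
  cm <- simulate_current_density_cohort(cohort_config(n_subjects = 8,
                                                      seed = 3))
  expect_true(all(cm$maps >= 0))
  expect_equal(rowSums(cm$maps), rep(1, 8), tolerance = 1e-12)
})

test_that("fast-path output shapes follow the contract", {
  cm <- simulate_current_density_cohort(cohort_config(n_subjects = 4,
                                                      seed = 1),
                                        n_voxels = 3)
  expect_equal(dim(cm$maps), c(4, 3))
  expect_equal(length(cm$behavior), 4)
  cmc <- simulate_current_density_cohort(cohort_config(n_subjects = 5,
                                                       seed = 1),
                                         n_voxels = 10, n_cycles = 3)
  expect_equal(length(cmc$cycle_maps), 3)
  expect_equal(dim(cmc$cycle_maps[[2]]), c(5, 10))
  expect_equal(dim(cmc$cycle_durations), c(5, 3))
})

test_that("at strong planted effects the max-|r| peak sits in the effect voxel's immediate neighborhood", {
  hits <- vapply(1:100, function(s) {
    cm <- simulate_current_density_cohort(
      cohort_config(n_subjects = 52, r_true = 0.9, seed = 300 + s))
    rs <- cor(log10(cm$maps), cm$behavior)
    pk <- which.max(abs(rs))
    d <- sqrt(sum((cm$grid[pk, c("x", "y", "z")] -
                     cm$grid[cm$effect_voxel, c("x", "y", "z")])^2))
    d <= 5 * sqrt(3) + 1e-9
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("whole-brain correction recovers the planted effect and the ROI correlation", {
  hits <- logical(50)
  roi_dev <- numeric(50)
  for (s in 1:50) {
    cfg <- cohort_config(n_subjects = 52, r_true = -0.6, seed = s)
    cm <- simulate_current_density_cohort(cfg)
    lg <- log10(cm$maps)
    pr <- permutation_fwer_threshold(lg, cm$behavior, cm$tst_min,
                                     n_perm = 500, seed = s, grid = cm$grid)
    cl <- extract_clusters(pr)
    hits[s] <- cm$effect_voxel %in% unlist(attr(cl, "members"))
    pk <- which.max(abs(pr$statmap$stats$r))
    roi <- build_roi_sphere(unlist(cm$grid[pk, c("x", "y", "z")]), 15,
                            cm$grid)
    rhat <- partial_correlation(roi_mean_density(lg, roi), cm$behavior,
                                cm$tst_min)$r
    roi_dev[s] <- abs(rhat - cor(cm$cohort$source_amp, cm$behavior))
  }
  expect_gte(mean(hits), 0.8)
  expect_lte(median(roi_dev), 0.15)
})
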