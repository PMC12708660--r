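test_that("partial correlation agrees with the precision-matrix oracle", {
  set.seed(11)
  for (i in 1:10) {
    x <- rnorm(20)
    z <- rnorm(20)
    y <- 0.5 * x - 0.3 * z + rnorm(20)
    expect_equal(partial_correlation(x, y, z)$r,
                 oracle_partial_correlation(x, y, z), tolerance = 1e-12)
  }
  # the spec's small example, against the same independent route
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  z <- c(1, 1, 2, 2, 3)
  expect_equal(partial_correlation(x, y, z)$r,
               oracle_partial_correlation(x, y, z), tolerance = 1e-12)
})

test_that("a constant covariate column reduces to the plain Pearson r", {
  set.seed(4)
  x <- rnorm(15)
  y <- rnorm(15)
  res <- partial_correlation(x, y, covariates = rep(1, 15))
  expect_equal(res$r, cor(x, y), tolerance = 1e-12)
  expect_equal(res$df, 13)
  expect_error(partial_correlation(x, rep(2, 15)), "zero residual variance")
})

test_that("vectorized voxel-wise map equals the per-voxel loop oracle", {
  set.seed(21)
  maps <- matrix(rnorm(10 * 20), 10)
  behavior <- rnorm(10)
  cov <- rnorm(10)
  sm <- voxelwise_partial_correlation(maps, behavior, cov)
  expect_equal(sm$stats$r, oracle_voxel_loop(maps, behavior, cov),
               tolerance = 1e-12)
  # exchange invariance: consistent subject reordering leaves the map alone
  p <- sample(10)
  sm2 <- voxelwise_partial_correlation(maps[p, ], behavior[p], cov[p])
  expect_equal(sm2$stats$r, sm$stats$r, tolerance = 1e-12)
  # behavior identical to one voxel's values -> that voxel r = 1
  sm3 <- voxelwise_partial_correlation(maps, maps[, 7])
  expect_equal(sm3$stats$r[7], 1, tolerance = 1e-12)
  # constant voxels are excluded with a warning
  maps[, 3] <- 5
  expect_warning(sm4 <- voxelwise_partial_correlation(maps, behavior, cov),
                 "constant voxel")
  expect_true(is.na(sm4$stats$r[3]))
})

test_that("critical |r| inverts the t transform", {
  expect_equal(round(critical_r(52), 3), 0.273)
  r <- critical_r(30, alpha = 0.01, k = 2)
  expect_equal(partial_correlation(seq_len(30), seq_len(30))$df, 28)
  t <- r * sqrt((30 - 4) / (1 - r^2))
  expect_equal(2 * pt(-t, 30 - 4), 0.01, tolerance = 1e-12)
})

test_that("Monte-Carlo null with all distinct permutations equals exhaustive enumeration", {
  set.seed(33)
  n <- 5
  maps <- matrix(rnorm(n * 3), n)
  behavior <- rnorm(n)
  cov <- rnorm(n)
  perms <- all_permutations(n)  # 120 columns
  pr <- permutation_fwer_threshold(maps, behavior, cov,
                                   perm_matrix = perms)
  # oracle: residualize, permute, correlate per voxel with plain loops
  X <- cbind(1, cov)
  Q <- diag(n) - X %*% solve(crossprod(X), t(X))
  e <- drop(Q %*% behavior)
  null_oracle <- apply(perms, 2, function(p) {
    ystar <- drop(Q %*% e[p])
    max(abs(vapply(1:3, function(v) {
      cor(drop(Q %*% maps[, v]), ystar)
    }, 0)))
  })
  expect_equal(sort(pr$null_max), sort(null_oracle), tolerance = 1e-12)
})

test_that("raising alpha never shrinks the significant set", {
  cm <- simulate_current_density_cohort(
    cohort_config(n_subjects = 30, r_true = -0.7, seed = 6), n_voxels = 50)
  lg <- log10(cm$maps)
  sets <- lapply(c(0.01, 0.05, 0.10), function(a) {
    which(permutation_fwer_threshold(lg, cm$behavior, cm$tst_min,
                                     n_perm = 199, alpha = a,
                                     seed = 5)$significant)
  })
  expect_true(all(sets[[1]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[3]]))
})

test_that("permutation guards: constant behavior errors, small n warns", {
  maps <- matrix(rnorm(20), 5)
  expect_error(
    suppressWarnings(permutation_fwer_threshold(maps, rep(1, 5),
                                                n_perm = 10, seed = 1)),
    "constant")
  expect_warning(permutation_fwer_threshold(maps, rnorm(5), n_perm = 10,
                                            seed = 1),
                 "n_perm < 100")
})

test_that("cluster extraction matches a flood-fill oracle on random masks", {
  grid <- default_lead_field()$grid
  set.seed(9)
  for (i in 1:5) {
    mask <- runif(nrow(grid)) < 0.12
    if (!any(mask)) next
    stats <- dplyr::mutate(grid, r = rnorm(nrow(grid)))
    cl <- extract_clusters(stats, mask = mask)
    oracle <- oracle_flood_fill(stats[mask, c("x", "y", "z")], 5)
    expect_equal(nrow(cl), length(unique(oracle)))
    expect_equal(sort(cl$n_voxels), sort(as.vector(table(oracle))))
  }
})

test_that("cluster geometry: 4 adjacent voxels form one 500 mm^3 cluster", {
  grid <- default_lead_field()$grid
  # a 2x2 plaquette of laterally adjacent voxels
  target <- grid$voxel[grid$x %in% c(-2.5, 2.5) & grid$y %in% c(-2.5, 2.5) &
                         grid$z == 27.5]
  mask <- grid$voxel %in% target
  stats <- dplyr::mutate(grid, r = -0.5)
  cl <- extract_clusters(stats, mask = mask)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_voxels, 4)
  expect_equal(cl$size_mm3, 500)
  # peak ties break at the lowest voxel index
  expect_equal(cl$peak_voxel, min(target))
  # two voxels >= 2 grid steps apart are two clusters
  mask2 <- grid$voxel %in% grid$voxel[c(1, 3)]
  cl2 <- extract_clusters(stats, mask = mask2)
  expect_equal(nrow(cl2), 2)
  # empty mask -> empty set
  expect_equal(nrow(extract_clusters(stats, mask = rep(FALSE, nrow(grid)))), 0)
})

test_that("spherical ROIs enumerate the right lattice points", {
  big <- swabias:::voxel_lattice(13, 5, c(0, 0, 0))
  roi <- build_roi_sphere(c(0, 0, 0), 15, big)
  expect_equal(length(roi$members), 123)  # lattice points with i^2+j^2+k^2 <= 9
  roi0 <- build_roi_sphere(c(0, 0, 0), 0, big)
  expect_equal(length(roi0$members), 1)
  expect_error(build_roi_sphere(c(1000, 0, 0), 5, big), "does not intersect")
})

test_that("mirroring flips x, preserves cardinality, and is an involution", {
  grid <- default_lead_field()$grid
  roi <- build_roi_sphere(c(-12.5, -7.5, 37.5), 15, grid)
  m <- mirror_roi(roi)
  expect_equal(m$center, c(12.5, -7.5, 37.5))
  expect_equal(length(m$members), length(roi$members))
  expect_equal(sort(mirror_roi(m)$members), sort(roi$members))
  # the paper-style coordinate flip
  roi2 <- build_roi_sphere(c(-55, -35, 30), 200, grid)
  expect_equal(mirror_roi(roi2)$center, c(55, -35, 30))
})

test_that("ROI mean density matches hand values and is order-invariant", {
  grid <- tibble::tibble(voxel = 1:4, x = c(0, 5, 0, 5), y = 0,
                         z = c(0, 0, 5, 5))
  roi <- build_roi_sphere(c(2.5, 0, 2.5), 10, grid)
  expect_equal(length(roi$members), 4)
  expect_equal(roi_mean_density(c(-1, -0.5, -0.5, -2), roi), -1)
  m <- matrix(c(-1, -0.5, -0.5, -2,
                -2, -1, -1, -4), 2, 4, byrow = TRUE)
  expect_equal(roi_mean_density(m, roi), c(-1, -2))
  roi_shuffled <- roi
  roi_shuffled$members <- rev(roi$members)
  expect_equal(roi_mean_density(c(-1, -0.5, -0.5, -2), roi_shuffled), -1)
})

test_that("Meng's test follows the published formula chain", {
  # equal correlations -> Z = 0, one-sided p = 0.5
  eq <- meng_dependent_correlation_test(0.4, 0.4, 0.3, 40)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_one_sided, 0.5)
  # hand-evaluated chain at the study's n
  res <- meng_dependent_correlation_test(-0.45, -0.20, 0.50, 52)
  expect_equal(res$z, -1.883, tolerance = 1e-3)
  expect_equal(res$p_one_sided, pnorm(-res$z), tolerance = 1e-12)
  expect_error(meng_dependent_correlation_test(1, 0.5, 0.3, 20), "Fisher z")
})

test_that("per-cycle analysis: identical cycles give identical correlations", {
  cm <- simulate_current_density_cohort(
    cohort_config(n_subjects = 20, r_true = -0.6, seed = 8))
  raw <- cm$maps
  cycle_maps <- list(raw, raw, raw, raw)
  durations <- matrix(90, 20, 4)
  roi <- build_roi_sphere(
    unlist(cm$grid[cm$effect_voxel, c("x", "y", "z")]), 15, cm$grid)
  pc <- per_cycle_analysis(cycle_maps, cm$behavior, durations, roi,
                           pooled = FALSE)
  expect_equal(nrow(pc), 4)
  expect_equal(length(unique(round(pc$r, 12))), 1)
  expect_equal(pc$r_squared, pc$r^2, tolerance = 1e-12)
})

test_that("per-cycle analysis keeps the planted sign across cycles", {
  neg_all <- vapply(1:50, function(s) {
    cm <- simulate_current_density_cohort(
      cohort_config(n_subjects = 52, r_true = -0.6, seed = 400 + s),
      n_cycles = 4)
    roi <- build_roi_sphere(
      unlist(cm$grid[cm$effect_voxel, c("x", "y", "z")]), 15, cm$grid)
    pc <- per_cycle_analysis(cm$cycle_maps, cm$behavior, cm$cycle_durations,
                             roi, pooled = TRUE)
    all(pc$r < 0)
  }, TRUE)
  expect_gte(mean(neg_all), 0.9)
})

test_that("per-cycle analysis excludes subjects listwise and reports skips", {
  cm <- simulate_current_density_cohort(
    cohort_config(n_subjects = 10, r_true = 0, seed = 2), n_cycles = 2)
  maps <- cm$cycle_maps
  maps[[2]][c(1, 2), ] <- NA
  pc <- per_cycle_analysis(maps, cm$behavior, cm$cycle_durations,
                           build_roi_sphere(c(-12.5, -7.5, 37.5), 15,
                                            cm$grid),
                           cycles = 1:2, pooled = FALSE)
  expect_equal(pc$n, c(10, 8))
  maps[[2]][1:7, ] <- NA
  expect_warning(
    pc2 <- per_cycle_analysis(maps, cm$behavior, cm$cycle_durations,
                              build_roi_sphere(c(-12.5, -7.5, 37.5), 15,
                                               cm$grid),
                              cycles = 1:2, pooled = FALSE),
    "skipped")
  expect_equal(nrow(pc2), 1)
})
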