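# Synthetic cohort: latent traits, planted brain-behavior effect, and the
# fast current-density path that feeds the statistics directly.

#' Configuration of a synthetic cohort
#'
#' Bundles every tunable of the synthetic-data generator. Defaults emulate a
#' cohort of 52 healthy good sleepers whose absolute IAT D-scores have mean
#' 0.58 and SD ~0.27 and whose total sleep time averages ~435 min, with a
#' planted correlation `r_true` between the source amplitude at
#' `effect_voxel` and the behavioral trait.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param seed Integer master seed.
#' @param r_true Planted correlation in [-1, 1] between effect-voxel source
#'   amplitude and the behavioral trait (default -0.45).
#' @param effect_voxel Grid index of the planted source; `NULL` resolves to
#'   the left-lateral voxel nearest (-12.5, -7.5, 37.5) mm on the grid in use.
#' @param behavior_mean,behavior_sd Moments of the latent absolute D-score
#'   trait (normal, truncated below at 0.02).
#' @param tst_mean_min,tst_sd_min Moments of total sleep time in minutes
#'   (used directly by the fast path; the hypnogram generator realizes the
#'   same moments).
#' @param amp_mean,amp_cv Mean and coefficient of variation of the
#'   effect-voxel source amplitude (arbitrary source units).
#' @param map_noise_sd Log-scale SD of the spatially smooth voxel noise in
#'   the fast current-density path.
#' @param noise_smooth_mm Gaussian correlation length (mm) of that noise.
#' @param effect_lambda Planted-effect strength at the effect voxel, as a
#'   multiple of `map_noise_sd`.
#' @param effect_kernel_mm Spatial Gaussian width (mm) of the planted effect.
#' @param channel_noise_sd Scalp sensor noise SD in microvolts (EEG path).
#' @param rate EEG sampling rate in Hz (default 500).
#' @param cycle_scale Hypnogram template scale (< 1 gives short nights for
#'   desk-scale simulation).
#' @param artifact_prob Probability that an epoch's sensor noise is inflated
#'   8-fold, emulating movement artifacts.
#' @return A list of class `swa_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 52,
                          seed = 1,
                          r_true = -0.45,
                          effect_voxel = NULL,
                          behavior_mean = 0.58,
                          behavior_sd = 0.19,
                          tst_mean_min = 435.5,
                          tst_sd_min = 26,
                          amp_mean = 1,
                          amp_cv = 0.3,
                          map_noise_sd = 0.25,
                          noise_smooth_mm = 8,
                          effect_lambda = 4,
                          effect_kernel_mm = 8,
                          channel_noise_sd = 6,
                          rate = 500,
                          cycle_scale = 1,
                          artifact_prob = 0.02) {
  assert_that(n_subjects >= 4, "n_subjects must be >= 4")
  assert_that(abs(r_true) <= 1, "|r_true| must be <= 1")
  assert_that(behavior_sd > 0 && tst_sd_min > 0 && map_noise_sd > 0 &&
                channel_noise_sd >= 0 && noise_smooth_mm > 0,
              "all spread parameters must be positive")
  structure(
    list(n_subjects = n_subjects, seed = seed, r_true = r_true,
         effect_voxel = effect_voxel, behavior_mean = behavior_mean,
         behavior_sd = behavior_sd, tst_mean_min = tst_mean_min,
         tst_sd_min = tst_sd_min, amp_mean = amp_mean, amp_cv = amp_cv,
         map_noise_sd = map_noise_sd, noise_smooth_mm = noise_smooth_mm,
         effect_lambda = effect_lambda, effect_kernel_mm = effect_kernel_mm,
         channel_noise_sd = channel_noise_sd, rate = rate,
         cycle_scale = cycle_scale, artifact_prob = artifact_prob),
    class = "swa_cohort_config"
  )
}

resolve_effect_voxel <- function(grid, config) {
  if (!is.null(config$effect_voxel)) return(as.integer(config$effect_voxel))
  target <- c(-12.5, -7.5, 37.5)
  d2 <- (grid$x - target[1])^2 + (grid$y - target[2])^2 + (grid$z - target[3])^2
  which.min(d2)
}

#' Simulate cohort latent traits
#'
#' Draws, per subject, a latent behavioral trait (the "true" absolute
#' D-score, normal truncated below at 0.02) and a correlated source-amplitude
#' latent so that the correlation between effect-voxel amplitude and the
#' behavioral trait converges to `r_true`, plus a target total sleep time.
#'
#' @param config A [cohort_config()] object.
#' @param seed Overrides `config$seed` when given.
#' @return Tibble with columns `subject`, `z_behavior`, `z_source`,
#'   `behavior` (latent absolute D), `source_amp`, `tst_min`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  n <- config$n_subjects
  with_seed(seed, {
    z_b <- rnorm(n)
    z_eps <- rnorm(n)
    z_s <- config$r_true * z_b + sqrt(1 - config$r_true^2) * z_eps
    behavior <- pmax(config$behavior_mean + config$behavior_sd * z_b, 0.02)
    z_s_cl <- pmin(pmax(z_s, -3), 3)
    tibble(
      subject = sprintf("S%03d", seq_len(n)),
      z_behavior = z_b,
      z_source = z_s,
      behavior = behavior,
      source_amp = config$amp_mean * (1 + config$amp_cv * z_s_cl),
      tst_min = pmin(pmax(rnorm(n, config$tst_mean_min, config$tst_sd_min),
                          300), 560)
    )
  })
}

#' Fast path: simulate normalized current-density maps for a cohort
#'
#' Emulates the output of the localization stage directly: per subject a
#' nonnegative voxel map that sums to one, consisting of spatially smooth
#' log-normal noise plus a planted component at the effect voxel (Gaussian
#' spatial kernel, amplitude `effect_lambda` times the noise SD) carried by
#' the source latent that correlates `r_true` with the behavioral trait.
#'
#' @param config A [cohort_config()] object.
#' @param grid Voxel grid tibble (x, y, z in mm); defaults to a compact 5-mm
#'   lattice of `n_voxels` points (or the package default lead-field grid
#'   size, 216).
#' @param n_voxels Number of voxels when `grid` is not supplied.
#' @param n_cycles When given, additionally simulate per-sleep-cycle maps
#'   (shared subject field plus cycle-specific noise) and cycle durations.
#' @param seed Overrides `config$seed`.
#' @return List of class `swa_cohort_maps`: `maps` (subjects x voxels, rows
#'   sum to one), `behavior`, `tst_min`, `grid`, `effect_voxel`, `cohort`,
#'   `config`; with `n_cycles` also `cycle_maps` (list of matrices) and
#'   `cycle_durations` (subjects x cycles, minutes).
#' @export
simulate_current_density_cohort <- function(config, grid = NULL,
                                            n_voxels = NULL,
                                            n_cycles = NULL,
                                            seed = config$seed) {
  if (is.null(grid)) {
    nv <- n_voxels %||% 216
    n_axis <- ceiling(nv^(1 / 3))
    grid <- head(voxel_lattice(n_axis, 5, c(0, 0, 40)), nv)
    grid$voxel <- seq_len(nrow(grid))
  }
  nv <- nrow(grid)
  eff <- resolve_effect_voxel(grid, config)
  cohort <- simulate_cohort(config, seed = seed)
  n <- config$n_subjects

  xyz <- as.matrix(grid[, c("x", "y", "z")])
  D2 <- as.matrix(stats::dist(xyz))^2
  R <- chol(exp(-D2 / (2 * config$noise_smooth_mm^2)) + diag(1e-6, nv))
  kern <- exp(-D2[eff, ] / (2 * config$effect_kernel_mm^2))
  gamma <- config$effect_lambda * config$map_noise_sd

  build_maps <- function(L) {
    m <- exp(L)
    m / rowSums(m)
  }
  out <- with_seed(derive_seed(seed, 2), {
    L <- config$map_noise_sd * (matrix(rnorm(n * nv), n, nv) %*% R) +
      outer(cohort$z_source, gamma * kern)
    res <- list(maps = build_maps(L))
    if (!is.null(n_cycles)) {
      sigma_c <- 0.5 * config$map_noise_sd
      res$cycle_maps <- lapply(seq_len(n_cycles), function(k) {
        build_maps(L + sigma_c * (matrix(rnorm(n * nv), n, nv) %*% R))
      })
      res$cycle_durations <- matrix(
        pmax(rnorm(n * n_cycles, 90, 10), 30), n, n_cycles)
    }
    res
  })
  structure(
    c(out,
      list(behavior = cohort$behavior, tst_min = cohort$tst_min,
           grid = grid, effect_voxel = eff, cohort = cohort,
           config = config)),
    class = "swa_cohort_maps"
  )
}

#' @export
print.swa_cohort_maps <- function(x, ...) {
  cat(sprintf(
    "<swa_cohort_maps> %d subjects x %d voxels, r_true = %g (effect voxel %d)\n",
    nrow(x$maps), ncol(x$maps), x$config$r_true, x$effect_voxel))
  invisible(x)
}

#' Per-subject source amplitude profiles for the EEG path
#'
#' Builds the per-voxel source amplitude profile of each subject: a
#' deterministic smooth background (a handful of Gaussian hotspots shared by
#' everyone) plus the subject-specific amplitude at the effect voxel.
#'
#' @param cohort Tibble from [simulate_cohort()].
#' @param lead_field A [generate_lead_field()] object.
#' @param config A [cohort_config()] object.
#' @return Matrix subjects x voxels of nonnegative amplitudes (source units).
#' @export
cohort_source_profiles <- function(cohort, lead_field, config) {
  grid <- lead_field$grid
  eff <- resolve_effect_voxel(grid, config)
  xyz <- as.matrix(grid[, c("x", "y", "z")])
  centers <- matrix(c(0, 8, 50,
                      10, -8, 32,
                      -8, 10, 35), 3, 3, byrow = TRUE)
  base <- rep(0.25, nrow(grid))
  for (i in seq_len(nrow(centers))) {
    d2 <- rowSums(sweep(xyz, 2, centers[i, ])^2)
    base <- base + 0.75 * exp(-d2 / (2 * 10^2))
  }
  profiles <- matrix(rep(config$amp_mean * base, each = nrow(cohort)),
                     nrow(cohort), nrow(grid))
  profiles[, eff] <- profiles[, eff] + 1.5 * cohort$source_amp
  profiles
}
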