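# End-to-end pipeline: score -> preprocess -> spectra -> localize ->
# normalize -> correlate -> report.

#' Run the full brain-behavior pipeline on a study bundle
#'
#' For every valid subject: scores the IAT trials, preprocesses the night
#' EEG, epochs it with artifact masking, accumulates the SWA-band
#' cross-spectrum over artifact-free N2/N3 epochs (whole night and per sleep
#' cycle), localizes it with the standardized inverse and normalizes +
#' log-transforms the voxel map. Across subjects it then computes the
#' voxel-wise partial correlation between relative SWA current density and
#' the absolute D-score controlling for total sleep time, the max-statistic
#' permutation threshold, significant clusters, a spherical ROI around the
#' peak voxel with its mirrored contralateral ROI and Meng's laterality test,
#' and the per-cycle ROI analyses. Subjects failing any stage are excluded
#' with a logged reason; fewer than 4 usable subjects aborts.
#'
#' @param bundle A [load_study_bundle()] object.
#' @param lead_field Lead field matching the bundle's montage and grid
#'   (default [generate_lead_field()]).
#' @param snr Inverse-operator SNR setting (default 10).
#' @param n_perm Permutations for the FWER threshold.
#' @param alpha Corrected significance level.
#' @param seed Seed of the permutation stage (defaults to the bundle seed).
#' @param roi_radius_mm ROI sphere radius around the peak voxel.
#' @param band SWA band (Hz).
#' @param max_cycles Per-cycle analyses use at most this many cycles.
#' @param cycle_params List with `nrem_min` / `rem_min` passed to
#'   [detect_sleep_cycles()].
#' @return Object of class `swa_results`; see Details. Main tables:
#'   `behavior`, `architecture`, `per_cycle`, tidy `statmap` via
#'   [generics::tidy()], `clusters`, `roi` (left/right ROI correlations),
#'   `meng`, `excluded`, `provenance`.
#' @export
run_full_pipeline <- function(bundle,
                              lead_field = NULL,
                              snr = 10,
                              n_perm = 1000,
                              alpha = 0.05,
                              seed = NULL,
                              roi_radius_mm = 15,
                              band = c(0.8, 4.6),
                              max_cycles = 4,
                              cycle_params = list(nrem_min = 15, rem_min = 5)) {
  lf <- lead_field %||% generate_lead_field()
  assert_that(nrow(lf$grid) == nrow(bundle$grid),
              "lead field grid does not match the bundle grid")
  seed <- seed %||% bundle$seed %||% 1
  inv <- build_inverse_operator(lf, snr = snr)

  excluded <- dplyr::filter(bundle$subjects, !.data$ok) |>
    dplyr::transmute(subject = .data$id, reason = .data$issue)
  usable <- dplyr::filter(bundle$subjects, .data$ok)

  subj_res <- purrr::map(seq_len(nrow(usable)), function(i) {
    row <- usable[i, ]
    tryCatch(
      process_subject(row, lf, inv, band, max_cycles, cycle_params),
      error = function(e) {
        list(failed = sprintf("%s", conditionMessage(e)))
      })
  })
  failed <- vapply(subj_res, function(r) !is.null(r$failed), TRUE)
  if (any(failed)) {
    excluded <- dplyr::bind_rows(
      excluded,
      tibble(subject = usable$id[failed],
             reason = vapply(subj_res[failed], function(r) r$failed, "")))
  }
  subj_res <- subj_res[!failed]
  ids <- usable$id[!failed]
  n <- length(subj_res)
  if (n < 4) abort(sprintf("only %d usable subjects (need >= 4)", n))

  behavior_tbl <- dplyr::bind_cols(
    tibble(subject = ids),
    dplyr::bind_rows(purrr::map(subj_res, "dscore")))
  architecture_tbl <- dplyr::bind_cols(
    tibble(subject = ids),
    dplyr::bind_rows(purrr::map(subj_res, "architecture")))

  raw_maps <- do.call(rbind, purrr::map(subj_res, "map_values"))
  log_maps <- t(apply(raw_maps, 1, function(v) {
    log10(pmax(v / sum(v), 1e-12))
  }))
  behavior <- behavior_tbl$abs_d
  tst <- architecture_tbl$tst_min

  perm <- permutation_fwer_threshold(log_maps, behavior, tst,
                                     n_perm = n_perm, alpha = alpha,
                                     seed = derive_seed(seed, 77),
                                     grid = bundle$grid)
  clusters <- extract_clusters(perm)
  roi_tbl <- NULL
  meng <- NULL
  per_cycle <- NULL
  stats <- perm$statmap$stats
  peak <- which.max(abs(stats$r))
  roi <- build_roi_sphere(c(stats$x[peak], stats$y[peak], stats$z[peak]),
                          roi_radius_mm, bundle$grid)
  roi_m <- mirror_roi(roi)
  left_means <- roi_mean_density(log_maps, roi)
  right_means <- roi_mean_density(log_maps, roi_m)
  pc_left <- partial_correlation(left_means, behavior, tst)
  pc_right <- partial_correlation(right_means, behavior, tst)
  roi_tbl <- dplyr::bind_rows(
    dplyr::mutate(pc_left, side = "peak", .before = 1),
    dplyr::mutate(pc_right, side = "mirror", .before = 1))
  meng <- meng_dependent_correlation_test(
    cor(left_means, behavior), cor(right_means, behavior),
    cor(left_means, right_means), n)

  cycle_counts <- vapply(purrr::map(subj_res, "cycle_values"), length, 1L)
  n_cycles <- min(max_cycles, max(cycle_counts))
  if (n_cycles >= 1) {
    nv <- ncol(raw_maps)
    cycle_maps <- lapply(seq_len(n_cycles), function(k) {
      do.call(rbind, purrr::map(subj_res, function(r) {
        if (length(r$cycle_values) >= k) r$cycle_values[[k]]
        else rep(NA_real_, nv)
      }))
    })
    durations <- do.call(rbind, purrr::map(subj_res, function(r) {
      d <- r$cycle_durations
      c(d, rep(NA_real_, n_cycles))[seq_len(n_cycles)]
    }))
    per_cycle <- per_cycle_analysis(cycle_maps, behavior, durations, roi,
                                    cycles = seq_len(n_cycles))
  }

  structure(
    list(
      n = n,
      subjects = ids,
      behavior = behavior_tbl,
      architecture = architecture_tbl,
      spectra = dplyr::bind_rows(purrr::map2(
        subj_res, ids,
        function(r, id) dplyr::mutate(r$spectra_summary, subject = id,
                                      .before = 1))),
      maps = log_maps,
      statmap = perm$statmap,
      perm = perm,
      clusters = clusters,
      roi = roi,
      roi_mirror = roi_m,
      roi_correlations = roi_tbl,
      roi_means = tibble(subject = ids, peak = left_means,
                         mirror = right_means),
      meng = meng,
      per_cycle = per_cycle,
      excluded = excluded,
      provenance = list(
        package_version = as.character(utils::packageVersion("swabias")),
        seed = seed,
        n_perm = n_perm,
        alpha = alpha,
        snr = snr,
        band = band,
        config_hash = rlang::hash(bundle$config))
    ),
    class = "swa_results"
  )
}

process_subject <- function(row, lf, inv, band, max_cycles, cycle_params) {
  trials <- read_iat_csv(row$iat)
  dscore <- score_iat(trials)
  hyp <- read_hypnogram_csv(row$hypnogram)
  rec <- read_edf(row$edf)
  if (nrow(rec$data) != nrow(lf$electrodes)) {
    abort(sprintf("%d EEG channels but lead field has %d",
                  nrow(rec$data), nrow(lf$electrodes)))
  }
  rec$positions <- lf$electrodes
  rec <- preprocess_record(rec)
  ep <- epoch_and_mask_artifacts(rec, hyp)
  spectra <- compute_swa_spectra(ep, band = band)
  arch <- sleep_architecture(hyp)
  cycles <- do.call(detect_sleep_cycles, c(list(hyp), cycle_params))

  map <- localize_band_power(ep, inv, band = band)

  n_cyc <- min(nrow(cycles), max_cycles)
  cycle_values <- list()
  cycle_durations <- numeric(0)
  if (n_cyc >= 1) {
    cyc_idx <- epoch_cycle_index(hyp, cycles)
    for (k in seq_len(n_cyc)) {
      epk <- ep
      epk$epochs <- dplyr::mutate(
        ep$epochs, artifact = .data$artifact | cyc_idx != k |
          is.na(cyc_idx))
      mk <- tryCatch(localize_band_power(epk, inv, band = band),
                     error = function(e) NULL)
      if (is.null(mk)) break
      cycle_values[[k]] <- mk$values
      cycle_durations[k] <-
        (cycles$end_epoch[k] - cycles$start_epoch[k] + 1) *
        hyp$epoch_sec / 60
    }
  }
  list(
    dscore = dscore,
    architecture = arch,
    spectra_summary = tibble(channel = rec$channels,
                             swa_power = spectra$swa_band_power,
                             n_epochs = spectra$n_epochs_used),
    map_values = map$values,
    cycle_values = cycle_values,
    cycle_durations = cycle_durations
  )
}

#' @export
print.swa_results <- function(x, ...) {
  cat(sprintf("<swa_results> n = %d subjects (%d excluded)\n",
              x$n, nrow(x$excluded)))
  cat(sprintf("  critical |r| = %.3f (alpha = %g, %d permutations); %d significant voxel(s), %d cluster(s)\n",
              x$perm$critical_r, x$perm$alpha, x$perm$n_perm,
              sum(x$perm$significant), nrow(x$clusters)))
  pk <- x$roi_correlations[x$roi_correlations$side == "peak", ]
  cat(sprintf("  ROI partial r = %.3f (p = %.3g, R^2 = %.2f); Meng Z = %.2f, one-sided p = %.2f\n",
              pk$r, pk$p.value, pk$r_squared, x$meng$z, x$meng$p_one_sided))
  invisible(x)
}

#' @export
glance.swa_results <- function(x, ...) {
  pk <- x$roi_correlations[x$roi_correlations$side == "peak", ]
  tibble(
    n = x$n, n_excluded = nrow(x$excluded),
    critical_r = x$perm$critical_r,
    n_significant_voxels = sum(x$perm$significant),
    n_clusters = nrow(x$clusters),
    roi_r = pk$r, roi_p = pk$p.value, roi_r_squared = pk$r_squared,
    meng_z = x$meng$z, meng_p_one_sided = x$meng$p_one_sided
  )
}

#' Write a results bundle to disk
#'
#' Emits the main tables of a [run_full_pipeline()] result: behavior and
#' architecture CSVs, the stat map and subject maps as TSV, the permutation
#' null sample TSV, the cluster/ROI/Meng report and provenance as JSON, and
#' the per-cycle table.
#'
#' @param results A `swa_results` object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(results$behavior, file.path(dir, "behavior.csv"))
  readr::write_csv(results$architecture, file.path(dir, "architecture.csv"))
  readr::write_tsv(tidy(results$perm), file.path(dir, "statmap.tsv"))
  write_maps_matrix_tsv(results$maps, results$subjects,
                        file.path(dir, "maps_log10.tsv"))
  readr::write_tsv(tibble(null_max = results$perm$null_max),
                   file.path(dir, "permutation_null.tsv"))
  if (!is.null(results$per_cycle)) {
    readr::write_tsv(results$per_cycle, file.path(dir, "per_cycle.tsv"))
  }
  report <- list(
    n = results$n,
    excluded = results$excluded,
    critical_r = results$perm$critical_r,
    clusters = as.data.frame(results$clusters),
    roi = list(center = results$roi$center,
               radius_mm = results$roi$radius_mm,
               members = results$roi$members,
               correlations = results$roi_correlations),
    meng = results$meng,
    provenance = results$provenance
  )
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
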