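# swabias

Sleep deepens locally: the cortical topography of slow-wave activity (SWA,
0.8–4.6 Hz NREM EEG power) is a stable, person-specific "fingerprint" and a
candidate *neural trait* for explaining stable behavioral differences.
`swabias` implements, as a tested and reusable R pipeline, a whole-brain
analysis linking the *relative* intracortical distribution of sleep SWA to
implicit social bias measured with the race Implicit Association Test (IAT).
It is written for sleep/EEG researchers and biostatisticians who want the
full chain — behavioral scoring, sleep-EEG spectral analysis, standardized
source localization, and permutation-corrected brain–behavior statistics —
in one place, testable end to end without any external data.

The pipeline computes, per subject and then across subjects:

* **IAT D-score** — `D = (mean RT_incongruent − mean RT_congruent) / SD_pooled`,
  where the inclusive pooled SD spans all correct test-block trials; the
  analysis uses `|D|`, the strength of bias irrespective of direction.
* **Stage-gated SWA spectra** — zero-phase 0.5–40 Hz band-pass,
  spherical-spline interpolation of bad channels, average reference,
  semi-automatic artifact masking (moving-average thresholds in
  0.8–4.6 Hz and 20–40 Hz), Welch/Hann spectra of artifact-free N2/N3
  30-s epochs; sleep architecture (TST, efficiency, WASO, stage %) and
  Feinberg–Floyd sleep cycles from the hypnogram.
* **Standardized source maps** — a minimum-norm inverse
  `T = K'(KK' + αH)⁺` with `α = tr(KK')/(n_e·snr²)` on an analytic
  spherical head model, voxel estimates standardized by the resolution-matrix
  blocks (sLORETA standardization: zero localization error for noiseless
  single dipoles); SWA-band cross-spectra projected to per-voxel
  current-density power, normalized to a total of one and log10-transformed.
* **Brain–behavior inference** — voxel-wise partial Pearson correlations of
  relative SWA with `|D|` controlling total sleep time; family-wise error
  control by the max-|r| permutation distribution (Freedman–Lane scheme,
  `(k+1)/(n_perm+1)` critical-value convention); 26-connectivity clusters;
  15-mm spherical ROIs around the peak voxel; laterality mirroring
  (x-coordinate flip) with Meng's Z for dependent correlations; per-cycle
  repeats controlling each cycle's duration.

A seeded synthetic-data generator (`cohort_config()`, `simulate_cohort()`,
`simulate_current_density_cohort()`, `simulate_iat_trials()`,
`simulate_hypnogram()`, `simulate_sleep_night()`, `write_study_bundle()`)
emulates a 52-subject cohort of good sleepers — 59-channel whole-night EEG,
hypnograms, IAT trial tables — with a planted, tunable correlation between
the source amplitude at an effect voxel and the behavioral trait. See the
methods vignette (`vignettes/swa-bias-pipeline.Rmd`) for the models, the
calibration targets and every numerical choice.

## Worked example

Simulate a 52-subject cohort with a planted brain–behavior correlation of
−0.6 at one voxel, then run the whole-brain corrected analysis:

```r
library(swabias)

cfg    <- cohort_config(n_subjects = 52, r_true = -0.6, seed = 1)
cohort <- simulate_current_density_cohort(cfg)   # subjects x voxels, rows sum to 1
maps   <- log10(cohort$maps)

perm <- permutation_fwer_threshold(maps, cohort$behavior, cohort$tst_min,
                                   n_perm = 5000, alpha = 0.05, seed = 1,
                                   grid = cohort$grid)
perm
#> <swa_perm> 5000 permutations (freedman_lane), critical |r| = 0.471 at alpha = 0.05; 6 significant voxel(s)

extract_clusters(perm)
#>   cluster n_voxels size_mm3 peak_voxel     peak_r peak_x peak_y peak_z
#> 1       1        5      625        109 -0.5057239  -12.5  -12.5   42.5
#> 2       2        1      125          5  0.4731796    7.5  -12.5   27.5
```

The planted effect (at voxel 79, one lattice step from the cluster peak)
survives whole-brain correction: a 5-voxel (625 mm³) cluster of negative
correlations — higher relative SWA there goes with lower `|D|` — plus one
spurious single-voxel positive cluster, which a cluster-extent criterion
would drop. A 15-mm spherical ROI around the peak quantifies the
association:

```r
stats <- tidy(perm)
peak  <- stats[which.max(abs(stats$r)), ]
roi   <- build_roi_sphere(c(peak$x, peak$y, peak$z), 15, cohort$grid)
partial_correlation(roi_mean_density(maps, roi), cohort$behavior, cohort$tst_min)
#>            r      p.value df  n r_squared
#> 1 -0.4587298 0.0007103165 49 52  0.210433
```

The ROI partial correlation of −0.46 (p < 0.001, R² = 0.21) recovers the
planted effect at the strength and significance the study conditions are
calibrated to produce; for reference, the two-sided 5% critical value of an
uncorrected correlation at n = 52 is `critical_r(52)` = 0.273. Laterality is
probed by mirroring the ROI to the opposite hemisphere and comparing the two
dependent correlations with Meng's test
(`meng_dependent_correlation_test()`), and `per_cycle_analysis()` repeats
the ROI analysis per sleep cycle.

The same statistics run from raw synthetic nights — EDF recordings,
hypnogram CSVs and IAT CSVs on disk — via
`write_study_bundle(cfg, dir)`, `load_study_bundle(manifest)` and
`run_full_pipeline(bundle)`; a thin command-line wrapper with
`simulate` / `score-iat` / `localize` / `correlate` / `cycles` / `run-all`
subcommands lives at `inst/cli/swabias.R`.

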