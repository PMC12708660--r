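---
title: "Linking the cortical topography of sleep slow-wave activity to implicit bias: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking the cortical topography of sleep slow-wave activity to implicit bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swabias)
```

## The scientific question

Slow-wave activity (SWA) — EEG power in the low delta range, here 0.8–4.6 Hz,
during NREM sleep — is a proxy for sleep depth. Its cortical topography is
stable within a person and variable between people, which makes it a
candidate *neural trait* for explaining stable behavioral differences.
`swabias` implements a complete analysis chain for one such question: does
the *relative* regional distribution of SWA current density across the
cortex covary, across people, with the strength of implicit social bias as
measured by the race Implicit Association Test (IAT)?

The chain has five analysis stages plus a synthetic-data generator:

1. **IAT scoring** — per-trial tables to D-scores and absolute D-scores;
2. **sleep EEG** — filtering, bad-channel interpolation, average reference,
   30-s epoching with semi-automatic artifact masking, stage-gated Welch
   spectra, sleep architecture, Feinberg–Floyd sleep cycles;
3. **source localization** — a standardized minimum-norm inverse (the
   sLORETA standardization) on an analytic spherical head model, turning the
   SWA-band scalp cross-spectrum into per-voxel current-density power,
   normalized to a total of one and log10-transformed;
4. **brain–behavior statistics** — voxel-wise partial Pearson correlations
   (controlling total sleep time), whole-brain max-statistic permutation
   correction, cluster and spherical-ROI extraction, laterality mirroring
   with Meng's test for dependent correlations, and per-sleep-cycle repeats;
5. **I/O and orchestration** — EDF / CSV / TSV / JSON round-trips,
   study-bundle validation and `run_full_pipeline()`.

Because the package is developed and validated entirely against synthetic
data, the generator is itself first-class, tested code: it emulates a cohort
of 52 healthy good sleepers and plants a tunable correlation between the
source amplitude at one *effect voxel* and the behavioral trait, so that
every downstream stage can be checked for calibration, power and error
control.

## The synthetic cohort

`cohort_config()` collects every tunable. Per subject, `simulate_cohort()`
draws a standard-normal behavioral latent `z_b` and a source latent
`z_s = r_true * z_b + sqrt(1 - r_true^2) * eps`, so that the planted
correlation between the two is exactly `r_true` in distribution. The
behavioral trait — the subject's "true" absolute D-score — is
`0.58 + 0.19 * z_b`, truncated below at 0.02. The moments were chosen once
so that *scored* absolute D-scores (which add roughly
`sqrt(2/55) ≈ 0.19` of estimation noise from ~55 correct trials per
condition) come out with mean ≈ 0.58 and SD ≈ 0.27, the headline moments of
the emulated cohort; the truncation matches an observed range starting
at 0.03.

**IAT trials.** The seven-block structure is fixed: blocks 1–2 are 20-trial
category-learning blocks, blocks 3–4 the 60 congruent test trials, block 5 a
30-trial reversal practice, blocks 6–7 the 60 incongruent test trials — 190
trials in total. Trial RTs are log-normal with `sigma_log = 0.35` and a
congruent mean of 673.84 ms; within-subject trial SDs are then ~240–300 ms,
typical of IAT latencies. The incongruent blocks carry a multiplicative
log-RT shift solved by `uniroot()` so that the *population* D-score of the
generating process (mean shift over the inclusive pooled SD, including the
between-condition variance term) equals the subject's trait; this makes the
scored D an approximately unbiased, monotone readout of the trait. Error
rates are constant per condition (3.15% congruent, 7.53% incongruent),
which reproduces cohort-level error contrasts of the right size
(paired t ≈ 7–8 at n ≈ 60). Because the inclusive-SD D-score of a balanced
table is bounded near ±2, traits beyond the reachable range are clamped
with a warning.

**Hypnograms.** A deterministic five-cycle template
(W → N1 → N2 → N3 → N2 → REM → brief wake) with N3 declining and REM
expanding over the night, multiplicative log-normal jitter per segment
(SD 0.12) and a subject-level scale factor (SD 0.06) on sleep segments.
The template realizes, on cohort average, TST ≈ 435.5 min, efficiency
≈ 93%, WASO ≈ 22 min and stage percentages ≈ 7.8 / 46 / 24.5 / 21.3
(N1/N2/N3/REM) — the architecture of healthy young 7–8 h sleepers. The
`cycle_scale` parameter shrinks all segments proportionally to produce short
nights with the same grammar; simulations in the test suite use scales of
0.05–0.12 (25–60-minute nights) so that whole-pipeline checks stay
desk-scale.

**EEG nights.** The head model is a homogeneous conducting sphere
(R = 90 mm, σ = 0.33 S/m) with 59 electrodes on a Fibonacci cap and a
6×6×6 voxel lattice at 5-mm spacing, mirror-symmetric about x = 0 (so
laterality mirroring is exact) and strictly interior to the sphere. Dipole
potentials use the standard Legendre-series solution, validated against an
independent quadrature-constructed Neumann-correction oracle to ~1e-7
relative error. Each 30-s epoch contains, at the 16 strongest profile
voxels, a sum of eight random-phase sinusoids drawn uniformly over
0.8–4.6 Hz, amplitude-modulated by stage (N3 : N2 : N1 : REM : W =
1 : 0.5 : 0.15 : 0.06 : 0.04) and by an exponential overnight decline
(τ = 180 min of accumulated sleep), projected through the lead field, plus
white sensor noise (6 µV SD, inflated 8× in ~2% of epochs to emulate
movement artifacts). Scalp scaling is calibrated so N3 channel RMS is
~40 µV. What this generator deliberately does **not** emulate: spindle and
K-complex morphology, 1/f background spectra, realistic head geometry or
tissue conductivities, ocular/muscle artifacts with realistic topographies,
and circadian (as opposed to homeostatic) dynamics. Passing tests therefore
certify the *statistical machinery and its calibration*, not performance on
real recordings.

**Fast current-density path.** For statistical Monte-Carlo work the
generator can skip the EEG entirely: per subject a log-Gaussian voxel field
with squared-exponential spatial correlation (length 8 mm, log-SD 0.25),
plus a planted component `lambda * sd * exp(-d^2 / (2 * 8mm^2)) * z_s` at
the effect voxel with `lambda = 4`, exponentiated and normalized to unit
sum. The planted effect is spatially extended on purpose: a point effect
would make 15-mm ROI means mostly noise, whereas real SWA topographies vary
smoothly; with the 8-mm kernel, ROI-level correlation estimates track the
realized latent correlation to within ±0.15 and whole-brain correction
recovers a planted `r_true = -0.6` at n = 52 in ≳80% of seeds. The price is
that the voxel-wise |r| *peak* can land on an immediate lattice neighbour of
the effect voxel (it stays within one lattice step in ≈100% of seeds).

## Signal-processing choices

* **Band-pass filter (0.5–40 Hz):** linear-phase FIR (Hamming design,
  `signal::fir1`), applied once by FFT convolution with exact group-delay
  compensation — for a symmetric FIR this is zero-phase, with the same
  magnitude response as forward–backward filtering at half the cost on
  whole-night records. The tap count targets a 0.25-Hz transition at the low
  edge and is capped at a third of the record length so short test signals
  remain filterable; 60 Hz is attenuated by far more than 20 dB.
* **Bad channels:** spherical-spline interpolation (order m = 4, series to
  l = 50, regularization 1e-5) on unit-sphere electrode positions; a
  nearest-neighbours-on-the-sphere inverse-angle variant is available via
  `interp = "nearest"`.
* **Average reference** is applied after interpolation; per-sample channel
  means are zero to ~1e-9 µV, and all inverse operators are built on
  average-referenced gains, making maps invariant to common channel offsets.
* **Welch spectra:** 5-s periodic-Hann segments, 50% overlap, constant
  detrend, one-sided density normalization — 0.2 Hz bins, and a sinusoid of
  amplitude A integrates to A²/2 over the band within 2%. Band edges are
  inclusive.
* **Artifact masking:** an epoch is rejected when its channel-mean band
  power in 0.8–4.6 Hz (factor 2.0) *or* 20–40 Hz (factor 2.5) exceeds the
  factor times a centered moving average over the 15 nearest epochs of the
  same stage (edge-truncated, self included). The reference group is
  per-stage rather than pooled NREM: pooling N1 with N3 lets genuine
  stage differences in delta power masquerade as artifacts (>10% false
  rejections on clean synthetic nights). Lowering a factor can only grow
  the rejected set.
* **Sleep cycles:** NREM period ≥ 15 min followed by a REM period ≥ 5 min
  ends a cycle at the REM-period end; the night's first REM period is
  exempt from the minimum; shorter REM bouts are absorbed; wake neither
  breaks periods nor counts toward them; trailing NREM ≥ 15 min without REM
  closes a final cycle at the last sleep epoch. Both minima are parameters
  (scaled-down nights in tests use smaller ones).

## The inverse solution

`build_inverse_operator()` forms the Tikhonov minimum-norm transform
`T = K' (K K' + alpha * H)^+` on the average-referenced gain `K`, with `H`
the average-reference operator and `alpha = tr(K K') / (n_e * snr^2)` — the
standard mapping of an assumed amplitude SNR (default 10) to the
regularization weight; the exact internal of the original software is not
public, so `snr` is an exposed parameter. Voxel estimates are standardized
by the pseudo-inverted 3×3 diagonal blocks of the resolution matrix `T K`
(the sLORETA standardization), which gives exactly zero localization error
for noiseless single dipoles as `snr` grows — verified in the tests for 20
random dipole positions and orientations.

Band power is localized in the frequency domain: the scalp cross-spectrum
`C` is accumulated over Hann segments of all artifact-free N2/N3 epochs
restricted to 0.8–4.6 Hz bins, and the voxel value is
`tr(S_v^{-1} T_v C T_v')` — the standardized band current-density *power*
(for linear operators this is equivalent to time-domain filtering followed
by projection, at a fraction of the cost). Maps are then divided by their
voxel sum ("total current density of one", removing global-amplitude
confounds with no regional specificity) and log10-transformed with a 1e-12
floor. Per-cycle maps are normalized within each cycle before the log, so
every cycle contributes a *relative* topography.

## Statistics

* **Partial correlation** residualizes both variables on an intercept plus
  covariates and correlates the residuals; df = n − 2 − k; two-sided p from
  the t transform. At n = 52 without covariates the two-sided 5% critical
  value is |r| = 0.273.
* **Permutation correction** is Freedman–Lane by default: behavior is
  residualized on the covariates, residuals are permuted (seeded), the
  covariate fit is re-added, and the maximum |r| across voxels is recorded
  per permutation. The critical value is the
  `ceiling((1 - alpha) * (n_perm + 1))`-th order statistic of the observed
  maximum pooled with the null maxima — including the observed value keeps
  the test exact at finite `n_perm`. Raw-label permutation is available via
  `scheme = "labels"`, and an explicit permutation matrix can be supplied
  (the tests use exhaustive enumeration at n = 5 against an independent
  loop oracle). Under the global null the realized family-wise error over
  200 synthetic cohorts sits at the nominal 5% within binomial error.
* **Clusters** are connected components of the significant mask under
  26-connectivity (6-connectivity optional); cluster size is
  `count * spacing^3` mm³ and peak-voxel ties break at the lowest voxel
  index, for reproducibility.
* **ROIs** are grid∩sphere sets (radius 15 mm default; on an unrestricted
  5-mm lattice a 15-mm sphere holds exactly 123 voxels). ROI means are
  computed on the log-transformed normalized values, consistent with the
  voxel-wise analysis. Mirroring flips the x-coordinates; on the symmetric
  lattice it is an involution that preserves cardinality.
* **Laterality** uses Meng's Z for dependent correlations sharing one
  variable, with `r12` the across-subject correlation between the two ROI
  mean densities. The one-sided (upper-tail) p is the headline — the
  reported Z/p pairing in this literature is only consistent with a
  one-sided tail — and the two-sided p is also returned.
* **Per-cycle analyses** are restricted to the first four cycles (fifth
  cycles are not universal), controlling for the duration of the specific
  cycle, with listwise exclusion of subjects lacking a cycle and a pooled
  cycles-2–4 analysis controlling the summed duration.

Two scoring-algorithm points were left open by the description the package
follows and are resolved as explicit options: error trials are *excluded*
by default (means of correct trials only), with the conventional 600-ms
error penalty behind `error_penalty = TRUE`; and D is computed on the
pooled test blocks by default, with the practice/test two-sub-D average
behind `two_block_d = TRUE`. Trials above 10 s are dropped and subjects
with >10% of RTs under 300 ms are flagged, the conventional defaults.
D-scores are never clamped to [−2, 2]; out-of-range values warn, since the
printed range is an empirical property of balanced tables rather than a
formula.

## Problem sizes used in validation

All validation is synthetic and sized to run on a single CPU in minutes:
FWER control uses 200 null cohorts (n = 52, 200 voxels) with 500
permutations each; planted-effect recovery and ROI calibration use 50
cohorts (n = 52, 216 voxels, `r_true = -0.6`, 500 permutations); the
peak-neighbourhood check uses 100 cohorts at `r_true = 0.9`; generator
calibration uses 20 cohorts of 52 subjects (hypnograms and scored IATs).
Full-EEG end-to-end checks use 59-channel nights of 25–65 minutes at
100 Hz (4–8 subjects): a paired-night monotonicity check (doubling the
effect-voxel amplitude raises its localized band power) and an
eight-subject amplitude-gradient recovery through preprocessing,
artifact masking, localization and normalization. The default
configuration (500 Hz, whole nights, n = 52) is the emulated study
condition and runs the same code path; the reduced sizes exercise every
stage end to end.

## Known limitations

* The spherical head model and 216-voxel interior lattice are a desk-scale
  stand-in for a realistic MNI-space solution space; absolute localization
  (in mm of real cortex) is not meaningful, only the statistical behavior
  of the chain is.
* The EEG generator's sinusoid-sum SWA has no realistic waveform morphology
  or 1/f background; artifact injection is white-noise inflation only.
* sLORETA standardization uses pseudo-inverses of the resolution blocks;
  with very low `snr` settings (heavy regularization) deep-voxel estimates
  become strongly smoothed, as expected of minimum-norm methods.
* Meng's test assumes bivariate-normal-ish sampling of the correlations;
  with n = 52 this is adequate, at very small n it is not.
* The hypnogram grammar produces idealized cycles; real nights with
  fragmented REM or missing cycles will exercise the listwise-exclusion
  paths more heavily than the synthetic cohorts do.
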