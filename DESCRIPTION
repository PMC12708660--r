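Package: swabias
Title: Sleep Slow-Wave Activity Topography and Implicit Bias
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline linking the intracortical distribution of
    sleep slow-wave activity (SWA, 0.8-4.6 Hz NREM EEG power) to implicit-bias
    scores. Implements Implicit Association Test (IAT) D-scoring, sleep-EEG
    preprocessing and stage-gated Welch spectra, sleep-architecture and
    Feinberg-Floyd sleep-cycle metrics, a desk-scale standardized minimum-norm
    (sLORETA-style) source localization on an analytic spherical head model,
    and whole-brain-corrected voxel-wise brain-behavior statistics (partial
    Pearson correlations, max-statistic permutation FWER control,
    cluster/spherical-ROI extraction, laterality mirroring with Meng's test,
    and per-sleep-cycle analyses). A seeded synthetic-data generator emulates
    a cohort of good sleepers with a planted, tunable brain-behavior effect so
    the whole pipeline is testable end to end without any external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
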