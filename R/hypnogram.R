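#' Hypnogram objects
#'
#' A hypnogram is a sequence of sleep-stage labels (`W`, `N1`, `N2`, `N3`,
#' `REM`), one per 30-s epoch, plus lights-off / lights-on markers delimiting
#' time in bed.
#'
#' @param stages Character vector of stage labels.
#' @param lights_off_epoch,lights_on_epoch Epoch indices delimiting time in
#'   bed (defaults: whole record).
#' @param epoch_sec Epoch length in seconds (30).
#' @return An object of class `swa_hypnogram`.
#' @export
hypnogram <- function(stages, lights_off_epoch = 1L,
                      lights_on_epoch = length(stages), epoch_sec = 30) {
  stages <- as.character(stages)
  bad <- setdiff(unique(stages), c("W", "N1", "N2", "N3", "REM"))
  if (length(bad) > 0) {
    abort(sprintf("unknown stage label(s): %s (first at epoch %d)",
                  paste(bad, collapse = ", "),
                  which(stages %in% bad)[1]))
  }
  assert_that(lights_off_epoch >= 1 && lights_off_epoch < lights_on_epoch &&
                lights_on_epoch <= length(stages),
              "lights markers must satisfy 1 <= lights_off < lights_on <= n")
  structure(
    list(stages = stages,
         lights_off_epoch = as.integer(lights_off_epoch),
         lights_on_epoch = as.integer(lights_on_epoch),
         epoch_sec = epoch_sec),
    class = "swa_hypnogram"
  )
}

#' @export
print.swa_hypnogram <- function(x, ...) {
  cat(sprintf("<swa_hypnogram> %d epochs (%.1f min), lights %d-%d\n",
              length(x$stages), length(x$stages) * x$epoch_sec / 60,
              x$lights_off_epoch, x$lights_on_epoch))
  print(table(x$stages))
  invisible(x)
}

#' @export
tidy.swa_hypnogram <- function(x, ...) {
  tibble(epoch = seq_along(x$stages), stage = x$stages)
}

#' Simulate a whole-night hypnogram of a good sleeper
#'
#' Deterministic cyclic stage grammar with seeded jitter. Each of five
#' NREM-REM cycles follows W -> N1 -> N2 -> N3 -> N2 -> REM (-> brief wake),
#' with deep sleep (N3) declining and REM expanding over the night. The base
#' template is calibrated so that, on cohort average, total sleep time is
#' about 435 min, sleep efficiency about 93%, WASO about 22 min and stage
#' percentages about 8/46/25/21 (N1/N2/N3/REM) - the architecture of a
#' healthy young 7-8 h sleeper.
#'
#' @param seed Integer seed.
#' @param cycle_scale Multiplies all template segment lengths; < 1 yields
#'   short nights with the same cyclic structure (used to keep simulations
#'   desk-scale).
#' @param tst_jitter_sd Subject-level log-scale SD applied to all sleep
#'   segments (night-to-night / person-to-person TST variation; default 0.06,
#'   about 26 min SD of TST).
#' @param segment_jitter_sd Log-scale SD of the per-segment jitter.
#' @return A [hypnogram()] object.
#' @export
simulate_hypnogram <- function(seed, cycle_scale = 1,
                               tst_jitter_sd = 0.06,
                               segment_jitter_sd = 0.12) {
  base <- list(
    latency = 12,
    n1  = c(14, 14, 14, 13, 13),
    n2a = c(37, 43, 49, 55, 57),
    n3  = c(80, 60, 40, 22, 12),
    n2b = c(25, 29, 33, 36, 38),
    rem = c(18, 28, 38, 48, 54),
    waso = c(11, 11, 11, 11, 0),
    terminal = 8
  )
  with_seed(seed, {
    jit <- function(len, sdlog) {
      pmax(1L, as.integer(round(len * exp(rnorm(length(len), 0, sdlog)
                                          - sdlog^2 / 2))))
    }
    subj <- exp(rnorm(1, 0, tst_jitter_sd) - tst_jitter_sd^2 / 2)
    stages <- c(rep("W", jit(base$latency * cycle_scale, segment_jitter_sd)))
    for (cyc in 1:5) {
      for (seg in c("n1", "n2a", "n3", "n2b", "rem")) {
        len <- jit(base[[seg]][cyc] * cycle_scale * subj, segment_jitter_sd)
        lab <- switch(seg, n1 = "N1", n2a = "N2", n3 = "N3",
                      n2b = "N2", rem = "REM")
        stages <- c(stages, rep(lab, len))
      }
      if (base$waso[cyc] > 0) {
        stages <- c(stages,
                    rep("W", jit(base$waso[cyc] * cycle_scale,
                                 segment_jitter_sd)))
      }
    }
    stages <- c(stages, rep("W", jit(base$terminal * cycle_scale,
                                     segment_jitter_sd)))
    hypnogram(stages)
  })
}
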