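#' Sleep architecture metrics from a hypnogram
#'
#' Computes total sleep time (TST, 0.5 min per sleep-stage epoch), sleep
#' efficiency (TST as a percentage of time in bed between the lights
#' markers), wake after sleep onset (WASO: wake minutes between the first
#' sleep epoch and the final awakening) and stage percentages relative to
#' TST. Sleep onset is the first epoch of any sleep stage (N1 counts).
#'
#' @param hyp A [hypnogram()] object.
#' @return One-row tibble: `tst_min`, `time_in_bed_min`,
#'   `sleep_efficiency_pct`, `waso_min`, `sleep_latency_min`, `pct_n1`,
#'   `pct_n2`, `pct_n3`, `pct_rem` (the four percentages sum to 100).
#' @export
#' @examples
#' h <- hypnogram(c("W", "W", "N1", "N2", "N3", "N3", "REM", "W", "N2"))
#' sleep_architecture(h)
sleep_architecture <- function(hyp) {
  idx <- hyp$lights_off_epoch:hyp$lights_on_epoch
  s <- hyp$stages[idx]
  sleep <- s != "W"
  if (!any(sleep)) abort("no sleep epochs: architecture undefined")
  epoch_min <- hyp$epoch_sec / 60
  tst <- sum(sleep) * epoch_min
  tib <- length(s) * epoch_min
  onset <- which(sleep)[1]
  last_sleep <- max(which(sleep))
  waso <- if (last_sleep > onset) {
    sum(s[onset:last_sleep] == "W") * epoch_min
  } else 0
  pct <- function(stage) 100 * sum(s == stage) / sum(sleep)
  tibble(
    tst_min = tst,
    time_in_bed_min = tib,
    sleep_efficiency_pct = 100 * tst / tib,
    waso_min = waso,
    sleep_latency_min = (onset - 1) * epoch_min,
    pct_n1 = pct("N1"),
    pct_n2 = pct("N2"),
    pct_n3 = pct("N3"),
    pct_rem = pct("REM")
  )
}

#' Detect NREM-REM sleep cycles in a hypnogram
#'
#' Adapted Feinberg & Floyd rules: a cycle is an NREM period containing at
#' least `nrem_min` minutes of NREM sleep followed by a REM period of at
#' least `rem_min` minutes (the night's first REM period is exempt from the
#' minimum). Wake epochs do not interrupt periods and count towards neither.
#' The cycle boundary sits at the end of the REM period; trailing NREM sleep
#' meeting the NREM minimum without subsequent REM closes a final cycle at
#' the last sleep epoch. REM periods too short to qualify are absorbed into
#' the ongoing cycle.
#'
#' @param hyp A [hypnogram()] object.
#' @param nrem_min Minimum NREM minutes per cycle (default 15).
#' @param rem_min Minimum REM minutes to terminate a cycle (default 5).
#' @return Tibble with columns `cycle`, `start_epoch`, `end_epoch`,
#'   `nrem_minutes`, `rem_minutes` (possibly zero rows).
#' @export
#' @examples
#' h <- hypnogram(c(rep("N2", 40), rep("REM", 12), rep("N2", 60), rep("REM", 20)))
#' detect_sleep_cycles(h)
detect_sleep_cycles <- function(hyp, nrem_min = 15, rem_min = 5) {
  idx <- hyp$lights_off_epoch:hyp$lights_on_epoch
  s <- hyp$stages[idx]
  epoch_min <- hyp$epoch_sec / 60
  sleep_pos <- which(s != "W")
  if (length(sleep_pos) == 0) return(empty_cycles())

  cls <- ifelse(s[sleep_pos] == "REM", "REM", "NREM")
  runs <- rle(cls)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1

  cycles <- list()
  cur_start <- sleep_pos[1]
  nrem_acc <- 0
  rem_acc <- 0
  seen_rem <- FALSE
  for (k in seq_along(runs$values)) {
    len_min <- runs$lengths[k] * epoch_min
    if (runs$values[k] == "NREM") {
      nrem_acc <- nrem_acc + len_min
    } else {
      first_rem <- !seen_rem
      seen_rem <- TRUE
      qualifies <- (len_min >= rem_min || first_rem) &&
        nrem_acc >= nrem_min
      if (qualifies) {
        end_pos <- sleep_pos[ends[k]]
        cycles[[length(cycles) + 1]] <- tibble(
          cycle = length(cycles) + 1L,
          start_epoch = idx[cur_start],
          end_epoch = idx[end_pos],
          nrem_minutes = nrem_acc,
          rem_minutes = rem_acc + len_min
        )
        nxt <- sleep_pos[sleep_pos > end_pos]
        cur_start <- if (length(nxt) > 0) nxt[1] else NA_integer_
        nrem_acc <- 0
        rem_acc <- 0
      } else {
        # short REM bout: absorbed into the ongoing cycle
        rem_acc <- rem_acc + len_min
      }
    }
  }
  if (!is.na(cur_start) && nrem_acc >= nrem_min) {
    cycles[[length(cycles) + 1]] <- tibble(
      cycle = length(cycles) + 1L,
      start_epoch = idx[cur_start],
      end_epoch = idx[sleep_pos[length(sleep_pos)]],
      nrem_minutes = nrem_acc,
      rem_minutes = rem_acc
    )
  }
  if (length(cycles) == 0) empty_cycles() else dplyr::bind_rows(cycles)
}

empty_cycles <- function() {
  tibble(cycle = integer(), start_epoch = integer(), end_epoch = integer(),
         nrem_minutes = numeric(), rem_minutes = numeric())
}

#' Map epochs to detected sleep cycles
#'
#' @param hyp A [hypnogram()] object.
#' @param cycles Output of [detect_sleep_cycles()].
#' @return Integer vector, one entry per epoch of the hypnogram: the cycle
#'   index covering that epoch, or `NA` outside any cycle.
#' @export
epoch_cycle_index <- function(hyp, cycles) {
  out <- rep(NA_integer_, length(hyp$stages))
  for (i in seq_len(nrow(cycles))) {
    out[cycles$start_epoch[i]:cycles$end_epoch[i]] <- cycles$cycle[i]
  }
  out
}
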