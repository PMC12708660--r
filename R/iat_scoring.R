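#' Score an Implicit Association Test trial table
#'
#' Computes the IAT D-score from a per-trial table of the seven-block race-IAT
#' layout: the mean response-time (RT) difference between the incongruent test
#' blocks (6-7) and the congruent test blocks (3-4), divided by the inclusive
#' standard deviation of all included trials pooled across both conditions.
#' Blocks 1, 2 and 5 are category-learning/practice blocks and never
#' contribute RTs. The absolute D-score (`abs_d`) quantifies bias strength
#' irrespective of direction.
#'
#' By default error trials are excluded and only correct-trial RTs enter the
#' means and the pooled SD. Setting `error_penalty = TRUE` switches to the
#' conventional revised-algorithm treatment instead: error RTs are replaced by
#' the block mean of correct trials plus 600 ms and all trials are included.
#'
#' @param trials Data frame with columns `block` (1-7), `rt_ms` (> 0) and
#'   `correct` (logical); extra columns are ignored.
#' @param error_penalty Replace error RTs by block-mean + 600 ms instead of
#'   excluding them (default `FALSE`).
#' @param two_block_d Compute separate D values for block pairs (3 vs 6) and
#'   (4 vs 7) and average them, instead of a single pooled D (default
#'   `FALSE`).
#' @param rt_max_ms Trials with RT above this are dropped (default 10000).
#' @param fast_rt_ms,fast_rt_prop A subject is flagged (`fast_flag`) when more
#'   than `fast_rt_prop` of test-block RTs are below `fast_rt_ms`.
#' @param min_trials Minimum usable trials per condition (default 10).
#'
#' @return A one-row tibble: `d`, `abs_d`, `mean_rt_congruent_ms`,
#'   `mean_rt_incongruent_ms`, `inclusive_sd_ms`, `n_trials_used`,
#'   `n_excluded`, `n_errors_congruent`, `n_errors_incongruent`, `fast_flag`,
#'   `bias_category` (none/weak/moderate/strong).
#' @export
#' @examples
#' trials <- tibble::tibble(
#'   block = c(3, 3, 6, 6), rt_ms = c(600, 700, 800, 900),
#'   correct = TRUE)
#' score_iat(trials, min_trials = 1)
score_iat <- function(trials,
                      error_penalty = FALSE,
                      two_block_d = FALSE,
                      rt_max_ms = 10000,
                      fast_rt_ms = 300,
                      fast_rt_prop = 0.10,
                      min_trials = 10) {
  assert_that(all(c("block", "rt_ms", "correct") %in% names(trials)),
              "trials needs columns block, rt_ms, correct")
  assert_that(all(trials$rt_ms > 0), "rt_ms must be positive")

  test <- dplyr::filter(trials, .data$block %in% c(3, 4, 6, 7))
  test$condition <- ifelse(test$block %in% c(3, 4), "congruent", "incongruent")
  n_before <- nrow(test)
  kept <- dplyr::filter(test, .data$rt_ms <= rt_max_ms)
  n_excluded <- n_before - nrow(kept)
  fast_flag <- mean(kept$rt_ms < fast_rt_ms) > fast_rt_prop
  if (fast_flag) {
    warn("more than 10% of test-block RTs are implausibly fast; subject flagged")
  }

  n_err <- c(
    congruent = sum(!kept$correct[kept$condition == "congruent"]),
    incongruent = sum(!kept$correct[kept$condition == "incongruent"])
  )

  if (error_penalty) {
    kept <- kept |>
      dplyr::group_by(.data$block) |>
      dplyr::mutate(rt_ms = ifelse(.data$correct, .data$rt_ms,
                                   mean(.data$rt_ms[.data$correct]) + 600)) |>
      dplyr::ungroup()
  } else {
    kept <- dplyr::filter(kept, .data$correct)
  }

  for (cond in c("congruent", "incongruent")) {
    if (sum(kept$condition == cond) < min_trials) {
      abort(sprintf("too few usable trials in the %s condition (%d < %d)",
                    cond, sum(kept$condition == cond), min_trials))
    }
  }

  d_from <- function(df) {
    m <- tapply(df$rt_ms, df$condition, mean)
    s <- sd(df$rt_ms)
    if (!is.finite(s) || s <= 0) abort("zero pooled SD: degenerate trial table")
    unname((m["incongruent"] - m["congruent"]) / s)
  }

  if (two_block_d) {
    d1 <- d_from(dplyr::filter(kept, .data$block %in% c(3, 6)))
    d2 <- d_from(dplyr::filter(kept, .data$block %in% c(4, 7)))
    d <- (d1 + d2) / 2
  } else {
    d <- d_from(kept)
  }
  if (abs(d) > 2) {
    warn(sprintf("D-score %.3f falls outside the conventional [-2, 2] range", d))
  }

  tibble(
    d = d,
    abs_d = abs(d),
    mean_rt_congruent_ms = mean(kept$rt_ms[kept$condition == "congruent"]),
    mean_rt_incongruent_ms = mean(kept$rt_ms[kept$condition == "incongruent"]),
    inclusive_sd_ms = sd(kept$rt_ms),
    n_trials_used = nrow(kept),
    n_excluded = n_excluded,
    n_errors_congruent = unname(n_err["congruent"]),
    n_errors_incongruent = unname(n_err["incongruent"]),
    fast_flag = fast_flag,
    bias_category = bias_category(abs(d))
  )
}

#' Categorize absolute D-scores into conventional bias strength bands
#'
#' Cutpoints: `abs_d` <= 0.20 none/little, (0.20, 0.49] weak, (0.49, 0.74]
#' moderate, > 0.74 strong.
#'
#' @param abs_d Numeric vector of absolute D-scores.
#' @return Factor with levels none, weak, moderate, strong.
#' @export
bias_category <- function(abs_d) {
  cut(abs_d, breaks = c(-Inf, 0.20, 0.49, 0.74, Inf),
      labels = c("none", "weak", "moderate", "strong"), right = TRUE)
}

#' Cohort-level behavioral summary of IAT results
#'
#' Aggregates per-subject D-score rows (as returned by [score_iat()]): moments
#' and range of the absolute D-score, counts per bias category, and paired
#' t-tests comparing condition mean RTs and condition error counts across
#' subjects (t = mean difference / (sd of differences / sqrt(n)), df = n - 1).
#'
#' @param results Data frame with one row per subject holding at least
#'   `d`, `abs_d`, `mean_rt_congruent_ms`, `mean_rt_incongruent_ms`,
#'   `n_errors_congruent`, `n_errors_incongruent`.
#' @return A list of class `swa_behavior_summary` with elements `n`,
#'   `abs_d_mean`, `abs_d_sd`, `abs_d_range`, `rt_test`, `error_test`
#'   (each a tibble with estimate, statistic, df, p.value) and
#'   `category_counts`.
#' @export
summarize_cohort_behavior <- function(results) {
  assert_that(nrow(results) >= 2, "need at least 2 subjects")
  rt_test <- paired_t(results$mean_rt_incongruent_ms,
                      results$mean_rt_congruent_ms)
  error_test <- paired_t(results$n_errors_incongruent,
                         results$n_errors_congruent)
  structure(
    list(
      n = nrow(results),
      abs_d_mean = mean(results$abs_d),
      abs_d_sd = sd(results$abs_d),
      abs_d_range = range(results$abs_d),
      rt_test = rt_test,
      error_test = error_test,
      category_counts = dplyr::count(
        tibble(bias_category = bias_category(results$abs_d)),
        .data$bias_category, .drop = FALSE)
    ),
    class = "swa_behavior_summary"
  )
}

# Paired t-test on per-subject differences; errors on zero variance.
paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  s <- sd(d)
  if (!is.finite(s) || s == 0) {
    abort("zero variance of paired differences: t statistic undefined")
  }
  t <- mean(d) / (s / sqrt(n))
  tibble(estimate = mean(d), statistic = t, df = n - 1,
         p.value = 2 * pt(-abs(t), n - 1))
}

#' @export
print.swa_behavior_summary <- function(x, ...) {
  cat(sprintf("<swa_behavior_summary> n = %d\n", x$n))
  cat(sprintf("  |D|: mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              x$abs_d_mean, x$abs_d_sd, x$abs_d_range[1], x$abs_d_range[2]))
  cat(sprintf("  RT paired t(%d) = %.2f, p = %.3g\n",
              x$rt_test$df, x$rt_test$statistic, x$rt_test$p.value))
  cat(sprintf("  errors paired t(%d) = %.2f, p = %.3g\n",
              x$error_test$df, x$error_test$statistic, x$error_test$p.value))
  invisible(x)
}

#' @export
glance.swa_behavior_summary <- function(x, ...) {
  tibble(
    n = x$n, abs_d_mean = x$abs_d_mean, abs_d_sd = x$abs_d_sd,
    abs_d_min = x$abs_d_range[1], abs_d_max = x$abs_d_range[2],
    rt_statistic = x$rt_test$statistic, rt_p.value = x$rt_test$p.value,
    error_statistic = x$error_test$statistic,
    error_p.value = x$error_test$p.value
  )
}
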