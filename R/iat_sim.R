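#' Simulate one subject's IAT trial table
#'
#' Emulates the seven-block race-IAT layout (block sizes 20, 20, 30, 30, 30,
#' 30, 30 = 190 trials; blocks 3-4 congruent, 6-7 incongruent, 1, 2, 5
#' practice). Trial RTs are log-normal; the incongruent blocks carry a
#' multiplicative RT shift solved numerically so that the *population*
#' D-score of the generating process equals `trait` (the subject's latent
#' bias). Error rates are condition-specific constants calibrated to typical
#' accuracies of 97% (congruent) and 92% (incongruent).
#'
#' @param trait Latent signed bias of the subject on the D-score scale.
#' @param seed Integer seed; identical `trait` + `seed` give identical tables.
#' @param subject Optional subject identifier copied into the table.
#' @param rt_sigma_log SD of log RT within condition (default 0.35).
#' @param rt_mean_congruent_ms Mean congruent-trial RT in ms (default 673.84).
#' @param p_error_congruent,p_error_incongruent Per-trial error probabilities.
#' @return Tibble with columns `subject`, `block`, `trial`, `category`
#'   (positive-word / negative-word / face-A / face-B), `rt_ms`, `correct`.
#' @export
#' @examples
#' tr <- simulate_iat_trials(0.6, seed = 1)
#' nrow(tr)                   # 190
#' score_iat(tr)$abs_d
simulate_iat_trials <- function(trait, seed,
                                subject = NA_character_,
                                rt_sigma_log = 0.35,
                                rt_mean_congruent_ms = 673.84,
                                p_error_congruent = 0.0315,
                                p_error_incongruent = 0.0753) {
  assert_that(is.finite(trait), "trait must be finite")
  block_sizes <- c(20, 20, 30, 30, 30, 30, 30)
  meanlog_c <- log(rt_mean_congruent_ms) - rt_sigma_log^2 / 2
  delta <- iat_shift_for_trait(trait, rt_sigma_log)

  with_seed(seed, {
    rows <- purrr::map(1:7, function(b) {
      n <- block_sizes[b]
      cond <- iat_block_condition(b)
      meanlog <- meanlog_c + switch(cond,
        congruent = 0,
        incongruent = delta,
        practice = log(1.07))
      p_err <- switch(cond,
        congruent = p_error_congruent,
        incongruent = p_error_incongruent,
        practice = 0.05)
      cats <- iat_block_categories(b, n)
      tibble(
        subject = subject, block = b, trial = seq_len(n), category = cats,
        rt_ms = exp(meanlog + rt_sigma_log * rnorm(n)),
        correct = runif(n) >= p_err
      )
    })
    dplyr::bind_rows(rows)
  })
}

iat_block_condition <- function(block) {
  if (block %in% c(3, 4)) "congruent"
  else if (block %in% c(6, 7)) "incongruent"
  else "practice"
}

iat_block_categories <- function(block, n) {
  pool <- switch(as.character(block),
    "1" = c("positive-word", "negative-word"),
    "2" = c("face-A", "face-B"),
    c("positive-word", "face-A", "negative-word", "face-B"))
  rep_len(pool, n)
}

# Multiplicative log-RT shift of the incongruent condition whose population
# D-score (using the inclusive pooled SD of the two-condition RT mixture)
# equals the target trait. Monotone in the trait; solved by uniroot.
iat_shift_for_trait <- function(trait, sigma_log) {
  if (trait == 0) return(0)
  k2 <- exp(sigma_log^2) - 1
  d_pop <- function(delta) {
    m_c <- 1
    m_i <- exp(delta)
    v_pool <- (m_c^2 + m_i^2) * k2 / 2 + (m_i - m_c)^2 / 4
    (m_i - m_c) / sqrt(v_pool)
  }
  d_max <- 1 / sqrt(k2 / 2 + 1 / 4)  # asymptote as the shift grows
  target <- max(min(trait, d_max - 1e-3), -d_max + 1e-3)
  if (target != trait) {
    warn(sprintf("trait %.3f beyond reachable D range (+/-%.3f); clamped",
                 trait, d_max - 1e-3))
  }
  stats::uniroot(function(d) d_pop(d) - target, c(-12, 12), tol = 1e-10)$root
}

#' Simulate and score an IAT cohort
#'
#' Convenience wrapper: one trial table per subject (seeds derived from
#' `seed`), each scored with [score_iat()].
#'
#' @param traits Numeric vector of latent biases, one per subject.
#' @param seed Integer master seed.
#' @param ... Passed on to [simulate_iat_trials()] and [score_iat()] where
#'   applicable.
#' @return Tibble with one scored row per subject plus `subject` and `trait`.
#' @export
simulate_iat_cohort <- function(traits, seed, ...) {
  purrr::map_dfr(seq_along(traits), function(i) {
    tr <- simulate_iat_trials(traits[i], derive_seed(seed, i),
                              subject = sprintf("S%03d", i), ...)
    res <- score_iat(tr)
    dplyr::bind_cols(tibble(subject = sprintf("S%03d", i), trait = traits[i]),
                     res)
  })
}
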