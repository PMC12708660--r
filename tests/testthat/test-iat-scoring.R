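make_trials <- function(cong, incong) {
  tibble::tibble(
    block = c(rep(3, length(cong)), rep(6, length(incong))),
    rt_ms = c(cong, incong),
    correct = TRUE
  )
}

test_that("D-score matches the hand-computed pooled-SD example", {
  res <- score_iat(make_trials(c(600, 700), c(800, 900)), min_trials = 2)
  expect_equal(res$inclusive_sd_ms, sqrt(50000 / 3), tolerance = 1e-12)
  expect_equal(res$d, 200 / sqrt(50000 / 3), tolerance = 1e-12)
  expect_equal(res$d, 1.549, tolerance = 1e-3)
  expect_equal(res$abs_d, abs(res$d))
})

test_that("identical RT multisets in both conditions give d = 0", {
  res <- score_iat(make_trials(c(500, 600, 700), c(700, 600, 500)),
                   min_trials = 3)
  expect_equal(res$d, 0)
})

test_that("D is scale-equivariant, shift-sensitive, and sign-symmetric", {
  set.seed(5)
  cong <- 600 + 80 * rnorm(30)
  incong <- 750 + 90 * rnorm(30)
  d0 <- score_iat(make_trials(cong, incong))$d
  # multiplying every RT by c > 0 leaves d unchanged
  expect_equal(score_iat(make_trials(3 * cong, 3 * incong))$d, d0,
               tolerance = 1e-12)
  # adding a constant to all incongruent RTs strictly increases d
  expect_gt(score_iat(make_trials(cong, incong + 50))$d, d0)
  # swapping condition labels negates d, leaves abs_d unchanged
  swapped <- score_iat(make_trials(incong, cong))
  expect_equal(swapped$d, -d0, tolerance = 1e-12)
  expect_equal(swapped$abs_d, abs(d0), tolerance = 1e-12)
})

test_that("error trials are excluded by default and penalized on request", {
  tr <- make_trials(c(600, 700, 650, 620), c(800, 900, 850, 820))
  tr$correct[c(1, 5)] <- FALSE
  res <- score_iat(tr, min_trials = 3)
  expect_equal(res$n_trials_used, 6)
  expect_equal(res$n_errors_congruent, 1)
  expect_equal(res$n_errors_incongruent, 1)
  pen <- score_iat(tr, error_penalty = TRUE, min_trials = 3)
  expect_equal(pen$n_trials_used, 8)
  expect_gt(pen$mean_rt_congruent_ms, res$mean_rt_congruent_ms)
})

test_that("degenerate and undersized trial tables raise informative errors", {
  expect_error(score_iat(make_trials(c(600, 700), c(800, 900)),
                         min_trials = 10),
               "too few usable trials")
  same <- tibble::tibble(block = c(3, 3, 6, 6), rt_ms = 700, correct = TRUE)
  expect_error(score_iat(same, min_trials = 2), "zero pooled SD")
  # with equal condition sizes the inclusive-SD D is bounded near 2; an
  # unbalanced table with a huge shift pushes it beyond the printed range
  big <- make_trials(500 + seq_len(15), c(5000, 5100))
  expect_warning(score_iat(big, min_trials = 2), "outside the conventional")
})

test_that("blocks 1, 2 and 5 never contribute RTs to D", {
  tr <- make_trials(c(600, 700), c(800, 900))
  with_practice <- dplyr::bind_rows(
    tr,
    tibble::tibble(block = c(1, 2, 5), rt_ms = 10000, correct = TRUE))
  expect_equal(score_iat(with_practice, min_trials = 2)$d,
               score_iat(tr, min_trials = 2)$d)
})

test_that("bias categories follow the conventional cutpoints", {
  expect_equal(as.character(bias_category(c(0.1, 0.20, 0.35, 0.49, 0.58,
                                            0.74, 0.9))),
               c("none", "none", "weak", "weak", "moderate", "moderate",
                 "strong"))
})

test_that("cohort summary computes the paired t by hand-checkable formula", {
  res <- tibble::tibble(
    d = c(0.5, 0.7, 0.6, 0.4), abs_d = c(0.5, 0.7, 0.6, 0.4),
    mean_rt_congruent_ms = c(600, 650, 620, 640),
    mean_rt_incongruent_ms = c(600, 650, 620, 640) + c(50, 150, 100, 100),
    n_errors_congruent = c(1, 2, 1, 3),
    n_errors_incongruent = c(4, 5, 3, 6))
  s <- summarize_cohort_behavior(res)
  expect_equal(s$rt_test$statistic, 100 / (sqrt(5000 / 3) / 2),
               tolerance = 1e-12)
  expect_equal(s$rt_test$statistic, 4.899, tolerance = 1e-3)
  expect_equal(s$rt_test$df, 3)
  counts <- s$category_counts
  expect_equal(counts$n[counts$bias_category == "moderate"], 3)
  expect_equal(counts$n[counts$bias_category == "weak"], 1)
  # degenerate: zero variance of differences
  res$mean_rt_incongruent_ms <- res$mean_rt_congruent_ms + 100
  expect_error(summarize_cohort_behavior(res), "zero variance")
})
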