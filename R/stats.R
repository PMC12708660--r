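# Brain-behavior inference: partial correlations, max-statistic permutation
# FWER correction, Meng's test for dependent correlations.

#' Partial Pearson correlation
#'
#' Correlation between the residuals of `x` and `y` after least-squares
#' projection on an intercept plus `covariates`; df = n - 2 - k and the
#' two-sided p-value comes from the t transform `r * sqrt(df / (1 - r^2))`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Optional numeric matrix / data frame of k covariate
#'   columns (an intercept is always included).
#' @return One-row tibble: `r`, `p.value`, `df`, `n`, `r_squared`.
#' @export
#' @examples
#' partial_correlation(1:5, c(2, 1, 4, 3, 5), covariates = c(1, 1, 2, 2, 3))
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  assert_that(length(y) == n, "x and y must have equal length")
  X <- covariate_matrix(covariates, n)
  k <- ncol(X) - 1
  assert_that(n >= k + 3, "need n >= k + 3 observations")
  rx <- stats::lm.fit(X, x)$residuals
  ry <- stats::lm.fit(X, y)$residuals
  if (near_zero_spread(rx, x) || near_zero_spread(ry, y)) {
    abort("zero residual variance: partial correlation undefined")
  }
  r <- cor(rx, ry)
  df <- n - 2 - k
  t <- r * sqrt(df / (1 - r^2))
  tibble(r = r, p.value = 2 * pt(-abs(t), df), df = df, n = n,
         r_squared = r^2)
}

# Residual spread indistinguishable from rounding error of the raw scale.
near_zero_spread <- function(resid, raw) {
  sd(resid) <= 1e-10 * (sd(raw) + max(abs(raw)) + .Machine$double.xmin)
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1))
  Z <- as.matrix(covariates)
  assert_that(nrow(Z) == n, "covariate rows must match observations")
  # drop constant covariate columns (they are absorbed by the intercept)
  keep <- apply(Z, 2, function(z) sd(z) > 0)
  cbind(1, Z[, keep, drop = FALSE])
}

#' Critical |r| for a two-sided test
#'
#' The absolute correlation at which the two-sided p-value equals `alpha`
#' for a (partial) Pearson correlation with `n` observations and `k`
#' covariates: `t* / sqrt(df + t*^2)` with `t* = qt(1 - alpha/2, df)`.
#'
#' @param n Sample size.
#' @param alpha Two-sided significance level (default 0.05).
#' @param k Number of covariates (default 0).
#' @return Scalar critical |r|.
#' @export
#' @examples
#' critical_r(52)  # 0.273
critical_r <- function(n, alpha = 0.05, k = 0) {
  df <- n - 2 - k
  tstar <- qt(1 - alpha / 2, df)
  tstar / sqrt(df + tstar^2)
}

#' Voxel-wise partial correlation map
#'
#' Applies [partial_correlation()] to every voxel column of a subject x voxel
#' matrix (vectorized; identical to the per-voxel loop). Voxels constant
#' across subjects are excluded (r = NA) and reported with a warning.
#'
#' @param maps Numeric matrix, subjects x voxels.
#' @param behavior Numeric vector, one value per subject.
#' @param covariates Optional covariate matrix / vector.
#' @param grid Optional voxel grid tibble (x, y, z) carried into the result.
#' @param spacing_mm Voxel spacing carried into the result (default 5).
#' @return Object of class `swa_statmap`: list with `stats` tibble
#'   (`voxel`, `r`, `p.value`, optionally x/y/z), `n`, `k`, `df`, `grid`,
#'   `spacing_mm`.
#' @export
voxelwise_partial_correlation <- function(maps, behavior, covariates = NULL,
                                          grid = NULL, spacing_mm = 5) {
  maps <- as.matrix(maps)
  n <- nrow(maps)
  assert_that(length(behavior) == n, "behavior length must match map rows")
  X <- covariate_matrix(covariates, n)
  k <- ncol(X) - 1
  Q <- diag(n) - X %*% solve(crossprod(X), t(X))
  M <- Q %*% maps
  mnorm <- sqrt(colSums(M^2))
  excluded <- which(mnorm <= 1e-12 * max(mnorm, 1))
  if (length(excluded) > 0) {
    warn(sprintf("%d constant voxel(s) excluded: %s", length(excluded),
                 paste(head(excluded, 10), collapse = ", ")))
  }
  yr <- drop(Q %*% behavior)
  if (near_zero_spread(yr, behavior)) {
    abort("behavior constant after residualization")
  }
  r <- drop(crossprod(M, yr)) / (mnorm * sqrt(sum(yr^2)))
  r[excluded] <- NA_real_
  df <- n - 2 - k
  t <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  stats <- tibble(voxel = seq_len(ncol(maps)), r = r,
                  p.value = 2 * pt(-abs(t), df))
  if (!is.null(grid)) {
    stats <- dplyr::left_join(stats, grid, by = "voxel")
    spacing_mm <- infer_spacing(grid) %||% spacing_mm
  }
  structure(
    list(stats = stats, n = n, k = k, df = df, grid = grid,
         spacing_mm = spacing_mm, excluded = excluded),
    class = "swa_statmap"
  )
}

infer_spacing <- function(grid) {
  if (is.null(grid) || nrow(grid) < 2) return(NULL)
  ux <- sort(unique(grid$x))
  if (length(ux) > 1) min(diff(ux)) else NULL
}

#' @export
print.swa_statmap <- function(x, ...) {
  pk <- which.max(abs(x$stats$r))
  cat(sprintf(
    "<swa_statmap> %d voxels, n = %d (k = %d); peak |r| = %.3f at voxel %d\n",
    nrow(x$stats), x$n, x$k, abs(x$stats$r[pk]), pk))
  invisible(x)
}

#' @export
tidy.swa_statmap <- function(x, ...) x$stats

#' Max-statistic permutation threshold with family-wise error control
#'
#' Estimates the whole-brain corrected significance threshold for a
#' voxel-wise (partial) correlation map by permutation of the maximum
#' absolute correlation across voxels. With covariates the default scheme is
#' Freedman-Lane: the behavior is residualized on the covariates, the
#' residuals are permuted with a seeded generator, the covariate fit is added
#' back, and the voxel-wise |r| map is recomputed; each permutation
#' contributes its maximum across voxels. The critical value is the empirical
#' (1 - alpha) quantile of the observed-plus-null maxima (the
#' `ceiling((1 - alpha) * (n_perm + 1))`-th order statistic, which includes
#' the observed statistic and guarantees validity at finite `n_perm`);
#' voxels whose observed |r| exceeds it are marked significant.
#'
#' @inheritParams voxelwise_partial_correlation
#' @param n_perm Number of permutations (default 5000).
#' @param alpha Family-wise significance level (default 0.05).
#' @param seed Integer seed for the permutation generator.
#' @param scheme `"freedman_lane"` (permute covariate residuals) or
#'   `"labels"` (permute raw behavior values).
#' @param perm_matrix Optional explicit permutation matrix (n x n_perm), one
#'   permutation of `1:n` per column; overrides `n_perm` and `seed` (used for
#'   exhaustive enumeration at small n).
#' @return Object of class `swa_perm`: list with `statmap` (the observed
#'   [voxelwise_partial_correlation()]), `null_max` (vector of per-permutation
#'   max |r|), `critical_r`, `significant` (logical mask over voxels),
#'   `p_fwer` (per-voxel corrected p), `n_perm`, `alpha`, `seed`, `scheme`.
#' @export
permutation_fwer_threshold <- function(maps, behavior, covariates = NULL,
                                       n_perm = 5000, alpha = 0.05,
                                       seed = 1,
                                       scheme = c("freedman_lane", "labels"),
                                       grid = NULL,
                                       perm_matrix = NULL) {
  scheme <- match.arg(scheme)
  assert_that(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  maps <- as.matrix(maps)
  n <- nrow(maps)
  if (is.null(perm_matrix)) {
    if (n_perm < 100) warn("n_perm < 100: threshold estimate will be coarse")
    if (lfactorial(n) < log(n_perm)) {
      warn("more permutations requested than distinct orderings exist")
    }
  }
  obs <- voxelwise_partial_correlation(maps, behavior, covariates,
                                       grid = grid)
  ok <- setdiff(seq_len(ncol(maps)), obs$excluded)

  X <- covariate_matrix(covariates, n)
  Q <- diag(n) - X %*% solve(crossprod(X), t(X))
  M <- Q %*% maps[, ok, drop = FALSE]
  M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
  e <- drop(Q %*% behavior)  # Freedman-Lane permutes these residuals

  if (is.null(perm_matrix)) {
    perm_matrix <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
    })
  } else {
    perm_matrix <- as.matrix(perm_matrix)
    assert_that(nrow(perm_matrix) == n, "perm_matrix must have n rows")
    n_perm <- ncol(perm_matrix)
  }
  base <- if (scheme == "freedman_lane") e else behavior
  P <- matrix(base[perm_matrix], n, n_perm)
  E <- Q %*% P  # residualize the permuted outcome (no-op for freedman_lane without covariates)
  E <- sweep(E, 2, sqrt(colSums(E^2)), "/")
  null_max <- apply(abs(crossprod(M, E)), 2, max)

  obs_max <- max(abs(obs$stats$r[ok]))
  pooled <- sort(c(obs_max, null_max))
  crit <- pooled[ceiling((1 - alpha) * (n_perm + 1))]
  sig <- !is.na(obs$stats$r) & abs(obs$stats$r) > crit
  p_fwer <- vapply(obs$stats$r, function(rv) {
    if (is.na(rv)) return(NA_real_)
    (1 + sum(null_max >= abs(rv))) / (n_perm + 1)
  }, numeric(1))

  structure(
    list(statmap = obs, null_max = null_max, critical_r = crit,
         significant = sig, p_fwer = p_fwer, n_perm = n_perm,
         alpha = alpha, seed = seed, scheme = scheme),
    class = "swa_perm"
  )
}

#' @export
print.swa_perm <- function(x, ...) {
  cat(sprintf(
    "<swa_perm> %d permutations (%s), critical |r| = %.3f at alpha = %g; %d significant voxel(s)\n",
    x$n_perm, x$scheme, x$critical_r, x$alpha, sum(x$significant)))
  invisible(x)
}

#' @export
glance.swa_perm <- function(x, ...) {
  tibble(n_perm = x$n_perm, alpha = x$alpha, critical_r = x$critical_r,
         n_significant = sum(x$significant), scheme = x$scheme,
         seed = x$seed)
}

#' @export
tidy.swa_perm <- function(x, ...) {
  out <- x$statmap$stats
  out$significant <- x$significant
  out$p_fwer <- x$p_fwer
  out
}

#' Meng's test for two dependent correlations
#'
#' Z-test comparing two correlations `r1 = cor(x1, y)` and `r2 = cor(x2, y)`
#' that share the variable y, given `r12 = cor(x1, x2)`:
#' with Fisher transforms `z_i = atanh(r_i)`, mean square
#' `rbar2 = (r1^2 + r2^2) / 2`, `f = min(1, (1 - r12) / (2 (1 - rbar2)))` and
#' `h = (1 - f * rbar2) / (1 - rbar2)`,
#' `Z = (z1 - z2) * sqrt((n - 3) / (2 (1 - r12) h))`. The one-sided p-value
#' is the upper normal tail of Z; the two-sided p doubles the smaller tail.
#'
#' @param r1,r2 The two dependent correlations (|r| < 1).
#' @param r12 Correlation between the two predictors.
#' @param n Sample size (>= 4).
#' @return One-row tibble: `r1`, `r2`, `r12`, `n`, `z`, `p_one_sided`,
#'   `p_two_sided`.
#' @export
#' @examples
#' meng_dependent_correlation_test(-0.45, -0.20, 0.50, 52)
meng_dependent_correlation_test <- function(r1, r2, r12, n) {
  assert_that(abs(r1) < 1 && abs(r2) < 1,
              "|r1| and |r2| must be < 1 (Fisher z undefined at 1)")
  assert_that(abs(r12) <= 1, "|r12| must be <= 1")
  assert_that(n >= 4, "n must be >= 4")
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rbar2 <- (r1^2 + r2^2) / 2
  f <- min(1, (1 - r12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (z1 - z2) * sqrt((n - 3) / (2 * (1 - r12) * h))
  tibble(r1 = r1, r2 = r2, r12 = r12, n = n, z = z,
         p_one_sided = pnorm(z, lower.tail = FALSE),
         p_two_sided = 2 * pnorm(abs(z), lower.tail = FALSE))
}
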