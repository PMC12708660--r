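#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm runif qt pt pnorm qnorm sd cor var fft coef
#' @importFrom utils head tail
NULL

# Derive a reproducible child seed from a parent seed and an index.
# Kept strictly below .Machine$integer.max so set.seed() never overflows.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483629L) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# Normal draw truncated below at `lower` (simple rejection; lower is far in
# the tail for all defaults so this is effectively a single draw).
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

# Legendre polynomials P_1..P_nmax and derivatives P'_1..P'_nmax at x (vector).
# Returns list of two [length(x) x nmax] matrices. Uses the stable recurrences
#   (n+1) P_{n+1} = (2n+1) x P_n - n P_{n-1}
#   P'_{n+1} = (2n+1) P_n + P'_{n-1}
legendre_table <- function(x, nmax) {
  m <- length(x)
  P <- matrix(0, m, nmax)
  dP <- matrix(0, m, nmax)
  Pnm1 <- rep(1, m)      # P_0
  Pn <- x                # P_1
  dPnm1 <- rep(0, m)     # P'_0
  dPn <- rep(1, m)       # P'_1
  P[, 1] <- Pn
  dP[, 1] <- dPn
  if (nmax >= 2) {
    for (n in 1:(nmax - 1)) {
      Pnp1 <- ((2 * n + 1) * x * Pn - n * Pnm1) / (n + 1)
      dPnp1 <- (2 * n + 1) * Pn + dPnm1
      P[, n + 1] <- Pnp1
      dP[, n + 1] <- dPnp1
      Pnm1 <- Pn; Pn <- Pnp1
      dPnm1 <- dPn; dPn <- dPnp1
    }
  }
  list(P = P, dP = dP)
}

unit_rows <- function(m) m / sqrt(rowSums(m^2))

# Symmetric pseudo-inverse via eigen decomposition.
pinv_sym <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  if (!any(keep)) return(matrix(0, nrow(A), ncol(A)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}
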