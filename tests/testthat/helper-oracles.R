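# Independent oracles and shared fixtures for the test suite.

# ---- fixtures (built once per test run) -------------------------------------

.fixtures <- new.env(parent = emptyenv())

default_lead_field <- function() {
  if (is.null(.fixtures$lf)) .fixtures$lf <- generate_lead_field()
  .fixtures$lf
}

default_inverse <- function(snr = 1e6) {
  key <- paste0("inv", snr)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- build_inverse_operator(default_lead_field(), snr = snr)
  }
  .fixtures[[key]]
}

# ---- Gauss-Legendre quadrature ----------------------------------------------

gauss_legendre <- function(n) {
  i <- 1:(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}

# Legendre P_n and derivatives, independent simple recurrence (duplicated on
# purpose so the oracle does not share code with the package internals).
oracle_legendre <- function(x, nmax) {
  P <- matrix(0, length(x), nmax + 1)
  P[, 1] <- 1
  P[, 2] <- x
  for (n in 1:(nmax - 1)) {
    P[, n + 2] <- ((2 * n + 1) * x * P[, n + 1] - n * P[, n]) / (n + 1)
  }
  dP <- matrix(0, length(x), nmax + 1)
  dP[, 2] <- 1
  for (n in 1:(nmax - 1)) {
    dP[, n + 2] <- (2 * n + 1) * P[, n + 1] + dP[, n]
  }
  list(P = P[, -1, drop = FALSE], dP = dP[, -1, drop = FALSE])
}

# Oracle for the single-sphere EEG forward solution: free-space dipole
# potential plus a harmonic interior correction whose coefficients are found
# by projecting the numerically differentiated free-space potential on the
# boundary (Neumann condition) via Gauss-Legendre quadrature. Dipole on the
# z-axis at height f; moment q = (qx, 0, qz); evaluation at surface angle
# theta, azimuth phi; sphere radius R, conductivity sigma.
oracle_sphere_potential <- function(f, q, theta, phi, R, sigma = 0.33,
                                    nmax = 60, nq = 200) {
  vfree <- function(r, b, qq) {
    d <- r - b
    sum(qq * d) / (4 * pi * sigma * sum(d^2)^1.5)
  }
  b <- c(0, 0, f)
  gl <- gauss_legendre(nq)
  th <- acos(gl$x)
  pts <- cbind(sin(th), 0, cos(th))
  eps <- 1e-4
  leg <- oracle_legendre(gl$x, nmax)
  a_m0 <- a_m1 <- rep(0, nmax)
  if (abs(q[3]) > 0) {
    dV <- vapply(seq_along(gl$x), function(i) {
      p <- pts[i, ]
      (vfree((R + eps) * p, b, c(0, 0, q[3])) -
         vfree((R - eps) * p, b, c(0, 0, q[3]))) / (2 * eps)
    }, 0)
    for (n in 1:nmax) {
      g <- (2 * n + 1) / 2 * sum(gl$w * dV * leg$P[, n])
      a_m0[n] <- -g / (n * R^(n - 1))
    }
  }
  if (abs(q[1]) > 0) {
    dV <- vapply(seq_along(gl$x), function(i) {
      p <- pts[i, ]
      (vfree((R + eps) * p, b, c(q[1], 0, 0)) -
         vfree((R - eps) * p, b, c(q[1], 0, 0))) / (2 * eps)
    }, 0)
    Q <- sqrt(pmax(0, 1 - gl$x^2)) * leg$dP
    for (n in 1:nmax) {
      nrm <- 2 * n * (n + 1) / (2 * n + 1)
      g <- sum(gl$w * dV * Q[, n]) / nrm
      a_m1[n] <- -g / (n * R^(n - 1))
    }
  }
  xe <- cos(theta)
  lege <- oracle_legendre(xe, nmax)
  p_surf <- R * c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  vfree(p_surf, b, q) +
    sum(a_m0 * R^(1:nmax) * lege$P[1, ]) +
    sum(a_m1 * R^(1:nmax) * sqrt(max(0, 1 - xe^2)) * lege$dP[1, ]) * cos(phi)
}

# ---- statistics oracles ------------------------------------------------------

# Partial correlation from the inverse covariance (precision) matrix:
# r_xy.z = -P_xy / sqrt(P_xx P_yy), an algebraically independent route.
oracle_partial_correlation <- function(x, y, z) {
  S <- stats::cov(cbind(x, y, z))
  P <- solve(S)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# All permutations of 1:n as an n x n! matrix (recursive enumeration).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 1
  for (k in 1:n) {
    for (j in seq_len(ncol(sub))) {
      rest <- (1:n)[-k]
      out[, col] <- c(k, rest[sub[, j]])
      col <- col + 1
    }
  }
  out
}

# Flood-fill connected components over lattice coordinates (stack-based),
# independent of the igraph route used by the package.
oracle_flood_fill <- function(xyz, spacing, connectivity = 26) {
  n <- nrow(xyz)
  lim2 <- (spacing * (if (connectivity == 26) sqrt(3) else 1) * 1.001)^2
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack) > 0) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      d2 <- rowSums(sweep(xyz, 2, unlist(xyz[v, ]))^2)
      nb <- which(d2 <= lim2 & comp == 0L)
      comp[nb] <- cur
      stack <- c(stack, nb)
    }
  }
  comp
}

# Direct residualize-then-correlate using lm(), for the vectorized map path.
oracle_voxel_loop <- function(maps, behavior, covariates) {
  vapply(seq_len(ncol(maps)), function(v) {
    rx <- stats::residuals(stats::lm(maps[, v] ~ covariates))
    ry <- stats::residuals(stats::lm(behavior ~ covariates))
    stats::cor(rx, ry)
  }, 0)
}
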