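# Vertical finite-difference stencils on the per-column nonuniform grids.
#
# All vertical derivatives use 3-point Lagrange stencils, which are exact on
# quadratics including across the canopy-interface spacing jump. Boundary
# closures are chosen so the discrete operators are exact on quadratics
# satisfying the boundary conditions (no-slip value at the bed, zero slope at
# the free surface): this is what lets the analytic drag-free channel profile
# persist as a discrete steady state.

# Lagrange weights of the 3-point stencil {p0, p1, p2} for the derivative of
# order `deriv` (1 or 2) evaluated at `pe`. All arguments may be matrices.
lagrange3_weights <- function(p0, p1, p2, pe, deriv) {
  if (deriv == 1L) {
    w0 <- (2 * pe - p1 - p2) / ((p0 - p1) * (p0 - p2))
    w1 <- (2 * pe - p0 - p2) / ((p1 - p0) * (p1 - p2))
    w2 <- (2 * pe - p0 - p1) / ((p2 - p0) * (p2 - p1))
  } else {
    w0 <- 2 / ((p0 - p1) * (p0 - p2))
    w1 <- 2 / ((p1 - p0) * (p1 - p2))
    w2 <- 2 / ((p2 - p0) * (p2 - p1))
  }
  list(w0 = w0, w1 = w1, w2 = w2)
}

# Coefficient set for a vertical derivative on column grids z (n x N_k,
# one row per column), returned as three n x N_k matrices (lower, diag,
# upper) such that (D f)[, k] = lo[, k] f[, k-1] + di[, k] f[, k] +
# up[, k] f[, k+1].
#
# bottom = "dirichlet0": the field vanishes at z = 0 (bed); the k = 1 row
#   uses the stencil {0, z1, z2} with the bed value dropped.
# bottom = "onesided":   one-sided 3-point stencil {z1, z2, z3} (weights on
#   z3 folded into `up2` handling below is avoided by storing an extra
#   matrix; see `apply_dz`).
# top = "neumann0": zero slope at z = h (surface). For deriv = 2 the k = N_k
#   row is the curvature of the parabola through (z_{Nk-1}, z_Nk) with zero
#   slope at h; for deriv = 1 the slope of that parabola at z_Nk.
# top = "onesided": one-sided 3-point stencil.
make_dz_coefs <- function(z, h, deriv,
                          bottom = c("dirichlet0", "onesided"),
                          top = c("neumann0", "onesided")) {
  bottom <- match.arg(bottom)
  top <- match.arg(top)
  n <- nrow(z); N_k <- ncol(z)
  lo <- matrix(0, n, N_k); di <- matrix(0, n, N_k); up <- matrix(0, n, N_k)
  x2 <- matrix(0, n, N_k)  # weight on f[, k+2] (one-sided bottom row only)
  xm2 <- matrix(0, n, N_k) # weight on f[, k-2] (one-sided top row only)
  kk <- 2:(N_k - 1L)
  wi <- lagrange3_weights(z[, kk - 1L], z[, kk], z[, kk + 1L], z[, kk], deriv)
  lo[, kk] <- wi$w0; di[, kk] <- wi$w1; up[, kk] <- wi$w2
  # bottom row
  if (bottom == "dirichlet0") {
    wb <- lagrange3_weights(0 * z[, 1L], z[, 1L], z[, 2L], z[, 1L], deriv)
    di[, 1L] <- wb$w1; up[, 1L] <- wb$w2      # bed value is zero
  } else {
    wb <- lagrange3_weights(z[, 1L], z[, 2L], z[, 3L], z[, 1L], deriv)
    di[, 1L] <- wb$w0; up[, 1L] <- wb$w1; x2[, 1L] <- wb$w2
  }
  # top row
  if (top == "neumann0") {
    a <- z[, N_k - 1L] - h
    b <- z[, N_k] - h
    if (deriv == 2L) {
      lo[, N_k] <- 2 / (a^2 - b^2)
      di[, N_k] <- -2 / (a^2 - b^2)
    } else {
      # parabola A (z-h)^2 + C: slope at z_Nk is 2 A b
      lo[, N_k] <- 2 * b / (a^2 - b^2)
      di[, N_k] <- -2 * b / (a^2 - b^2)
    }
  } else {
    wt <- lagrange3_weights(z[, N_k - 2L], z[, N_k - 1L], z[, N_k],
                            z[, N_k], deriv)
    xm2[, N_k] <- wt$w0; lo[, N_k] <- wt$w1; di[, N_k] <- wt$w2
  }
  list(lo = lo, di = di, up = up, x2 = x2, xm2 = xm2)
}

# Apply a coefficient set to a field of the same shape.
apply_dz <- function(cf, f) {
  n <- nrow(f); N_k <- ncol(f)
  out <- cf$di * f
  out[, -1L] <- out[, -1L] + cf$lo[, -1L] * f[, -N_k]
  out[, -N_k] <- out[, -N_k] + cf$up[, -N_k] * f[, -1L]
  if (any(cf$x2[, 1L] != 0)) out[, 1L] <- out[, 1L] + cf$x2[, 1L] * f[, 3L]
  if (any(cf$xm2[, N_k] != 0))
    out[, N_k] <- out[, N_k] + cf$xm2[, N_k] * f[, N_k - 2L]
  out
}

# Scalar Thomas algorithm (used by the along-x free-surface solve and the
# 1D steady solver). a: sub-, b: main, c: super-diagonal, d: rhs.
thomas_solve <- function(a, b, c, d) {
  n <- length(b)
  cp <- numeric(n); dp <- numeric(n)
  cp[1L] <- c[1L] / b[1L]
  dp[1L] <- d[1L] / b[1L]
  for (i in 2:n) {
    m <- b[i] - a[i] * cp[i - 1L]
    cp[i] <- c[i] / m
    dp[i] <- (d[i] - a[i] * dp[i - 1L]) / m
  }
  x <- numeric(n)
  x[n] <- dp[n]
  for (i in (n - 1L):1L) x[i] <- dp[i] - cp[i] * x[i + 1L]
  x
}

# Vectorised Thomas solve of independent tridiagonal systems along the
# second index: row i solves, for k = 1..K,
#   lo[i,k] x[i,k-1] + di[i,k] x[i,k] + up[i,k] x[i,k+1] = d[i,k].
thomas_solve_rows <- function(lo, di, up, d) {
  K <- ncol(di)
  cp <- matrix(0, nrow(di), K)
  dp <- matrix(0, nrow(di), K)
  cp[, 1L] <- up[, 1L] / di[, 1L]
  dp[, 1L] <- d[, 1L] / di[, 1L]
  for (k in 2:K) {
    m <- di[, k] - lo[, k] * cp[, k - 1L]
    cp[, k] <- up[, k] / m
    dp[, k] <- (d[, k] - lo[, k] * dp[, k - 1L]) / m
  }
  x <- dp
  for (k in (K - 1L):1L) x[, k] <- dp[, k] - cp[, k] * x[, k + 1L]
  x
}
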