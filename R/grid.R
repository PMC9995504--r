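# Terrain-following (sigma) vertical mapping.
#
# Each column i carries N_kg equal layers filling [0, h_g(x_i)] (the canopy
# phase) and N_k - N_kg equal layers filling [h_g(x_i), h(x_i)] (the
# overflow), so the bed, the canopy top and the free surface always lie on
# fixed computational levels. The map is piecewise uniform per column; metric
# terms follow by second-order differences.

#' Build a terrain-following grid mapping
#'
#' @param h_g_profile canopy-top height per column (length `N_i`)
#' @param h_profile free-surface height per column (length `N_i`)
#' @param params a [sim_params()] object (supplies `N_i`, `N_k`, `N_kg`,
#'   `dx`)
#' @return an object of class `monami_mapping` with cell-center heights
#'   `z_c` (`N_i x N_k`), face heights `z_f` (`N_i x (N_k+1)`), layer
#'   thicknesses `dz`, per-column layer sizes `dzc` (canopy) and `dzo`
#'   (overflow), and the metric slope `dzdx_c` (`dz/dx` at constant sigma at
#'   cell centers)
#' @export
build_mapping <- function(h_g_profile, h_profile, params) {
  N_i <- params$N_i; N_k <- params$N_k; N_kg <- params$N_kg
  h_g_profile <- rep_len(h_g_profile, N_i)
  h_profile <- rep_len(h_profile, N_i)
  if (any(h_g_profile <= 0) || any(h_g_profile >= h_profile))
    stop("invalid geometry: need 0 < h_g < h in every column", call. = FALSE)
  N_ko <- N_k - N_kg
  dzc <- h_g_profile / N_kg
  dzo <- (h_profile - h_g_profile) / N_ko
  # faces: k = 0..N_k
  kf <- 0:N_k
  z_f <- matrix(0, N_i, N_k + 1L)
  can <- kf <= N_kg
  z_f[, can] <- outer(dzc, kf[can])
  z_f[, !can] <- h_g_profile + outer(dzo, kf[!can] - N_kg)
  z_c <- 0.5 * (z_f[, -(N_k + 1L), drop = FALSE] + z_f[, -1L, drop = FALSE])
  dz <- z_f[, -1L, drop = FALSE] - z_f[, -(N_k + 1L), drop = FALSE]
  dzdx_c <- ddx_matrix(z_c, params$dx)
  structure(list(hg = h_g_profile, h = h_profile,
                 N_i = N_i, N_k = N_k, N_kg = N_kg, dx = params$dx,
                 dzc = dzc, dzo = dzo,
                 z_c = z_c, z_f = z_f, dz = dz, dzdx_c = dzdx_c),
            class = "monami_mapping")
}

# d/dx along columns of an N_i x * matrix, second-order central with
# one-sided second-order ends.
ddx_matrix <- function(M, dx) {
  n <- nrow(M)
  D <- matrix(0, n, ncol(M))
  if (n >= 3L) {
    D[2:(n - 1L), ] <- (M[3:n, , drop = FALSE] -
                          M[1:(n - 2L), , drop = FALSE]) / (2 * dx)
    D[1L, ] <- (-3 * M[1L, ] + 4 * M[2L, ] - M[3L, ]) / (2 * dx)
    D[n, ] <- (3 * M[n, ] - 4 * M[n - 1L, ] + M[n - 2L, ]) / (2 * dx)
  }
  D
}

#' @exportS3Method base::print
print.monami_mapping <- function(x, ...) {
  cat(sprintf(
    "sigma mapping: %d columns x %d levels (%d canopy), h_g in [%.4f, %.4f], h in [%.4f, %.4f]\n",
    x$N_i, x$N_k, x$N_kg, min(x$hg), max(x$hg), min(x$h), max(x$h)))
  invisible(x)
}

# --- fractional vertical indexing ------------------------------------------

# Fractional cell-center index of physical heights zq (matrix, one row per
# column) in the piecewise-uniform column grids defined by hg, h. Integer
# part = lower bracketing center, fractional part = linear weight. Values
# below the first center give fi < 1, above the last give fi > N_k (callers
# clamp / anchor as appropriate).
frac_center_index <- function(zq, hg, h, N_kg, N_k) {
  N_ko <- N_k - N_kg
  dzc <- hg / N_kg
  dzo <- (h - hg) / N_ko
  lo_top <- hg - 0.5 * dzc    # last canopy center
  hi_bot <- hg + 0.5 * dzo    # first overflow center
  fi_can <- zq / dzc + 0.5
  fi_mid <- N_kg + (zq - lo_top) / (0.5 * (dzc + dzo))
  fi_ov <- N_kg + 1 + (zq - hi_bot) / dzo
  out <- fi_can
  mid <- zq > lo_top
  out[mid] <- fi_mid[mid]
  ov <- zq > hi_bot
  out[ov] <- fi_ov[ov]
  out
}

# Same for z-face grids (faces at k = 0..N_k; fractional index in face
# numbering 1..N_k+1 with face 1 the bed).
frac_face_index <- function(zq, hg, h, N_kg, N_k) {
  dzc <- hg / N_kg
  dzo <- (h - hg) / (N_k - N_kg)
  fi_can <- zq / dzc + 1
  fi_ov <- N_kg + 1 + (zq - hg) / dzo
  out <- fi_can
  ov <- zq > hg
  out[ov] <- fi_ov[ov]
  out
}

# --- vectorised monotone cubic (Fritsch-Carlson, as splinefun monoH.FC) ----

# zs, ys: n x m knot matrices (each row strictly increasing in zs);
# zq: n x q query matrix. Returns n x q values; queries beyond the knot range
# take the nearest knot value. Matches stats::splinefun(method = "monoH.FC")
# row by row, including the sequential slope filter.
interp_mono_rows <- function(zs, ys, zq, idx = NULL) {
  n <- nrow(zs); m <- ncol(zs)
  hx <- zs[, -1L, drop = FALSE] - zs[, -m, drop = FALSE]
  Sx <- (ys[, -1L, drop = FALSE] - ys[, -m, drop = FALSE]) / hx
  slope <- cbind(Sx[, 1L],
                 if (m > 2L) 0.5 * (Sx[, -1L, drop = FALSE] +
                                      Sx[, -(m - 1L), drop = FALSE]),
                 Sx[, m - 1L])
  # Fritsch-Carlson filter, sequential over intervals, vectorised over rows
  for (k in seq_len(m - 1L)) {
    Sk <- Sx[, k]
    zero <- which(Sk == 0)
    a <- slope[, k] / Sk
    b <- slope[, k + 1L] / Sk
    a2b3 <- 2 * a + b - 3
    ab23 <- a + 2 * b - 3
    adj <- which(a2b3 > 0 & ab23 > 0 & a * (a2b3 + ab23) < a2b3^2)
    if (length(adj)) {
      tauS <- 3 * Sk[adj] / sqrt(a[adj]^2 + b[adj]^2)
      slope[adj, k] <- tauS * a[adj]
      slope[adj, k + 1L] <- tauS * b[adj]
    }
    if (length(zero)) {
      slope[zero, k] <- 0
      slope[zero, k + 1L] <- 0
    }
  }
  # interval location per query (analytic index may be supplied)
  if (is.null(idx)) {
    idx <- matrix(1L, n, ncol(zq))
    for (k in 2:(m - 1L)) idx <- idx + (zq >= zs[, k])
  }
  lin0 <- rep.int(seq_len(n), ncol(zq)) + (as.vector(idx) - 1L) * n
  lin1 <- lin0 + n
  dmq <- dim(zq)
  z0 <- zs[lin0]; dim(z0) <- dmq
  z1 <- zs[lin1]; dim(z1) <- dmq
  y0 <- ys[lin0]; dim(y0) <- dmq
  y1 <- ys[lin1]; dim(y1) <- dmq
  m0 <- slope[lin0]; dim(m0) <- dmq
  m1 <- slope[lin1]; dim(m1) <- dmq
  hseg <- z1 - z0
  t <- (zq - z0) / hseg
  tc <- pmin(pmax(t, 0), 1)   # nearest-value beyond the range
  h00 <- (1 + 2 * tc) * (1 - tc)^2
  h10 <- tc * (1 - tc)^2
  h01 <- tc^2 * (3 - 2 * tc)
  h11 <- tc^2 * (tc - 1)
  h00 * y0 + h10 * hseg * m0 + h01 * y1 + h11 * hseg * m1
}

#' Re-map a cell-centered field between two grid mappings
#'
#' Columnwise monotone-cubic (Fritsch-Carlson) interpolation in physical
#' height from the old mapping's cell centers to the new mapping's cell
#' centers; values outside the old range take the nearest old value.
#' Identical mappings reproduce the field to machine precision, and any
#' field linear in z is reproduced exactly.
#'
#' @param field `N_i x N_k` matrix on `old_mapping` cell centers
#' @param old_mapping,new_mapping `monami_mapping` objects sharing
#'   `x_centers`
#' @return the field on `new_mapping` cell centers
#' @export
remap_field <- function(field, old_mapping, new_mapping) {
  stopifnot(old_mapping$N_i == new_mapping$N_i,
            old_mapping$N_k == new_mapping$N_k)
  if (identical(old_mapping$z_c, new_mapping$z_c)) return(field)
  interp_mono_rows(old_mapping$z_c, field, new_mapping$z_c)
}

# --- velocity sampling at arbitrary physical points ------------------------

# Bilinear sampler for cell-centered velocity fields: linear in x between
# columns, then linear in z within each column with the no-slip bed anchored
# (u = w = 0 at z = 0) and the top value extended above the last center.
# uc, wc: N_i x N_k center fields. Returns a function (X, Z) -> list(u, w)
# acting on matrices of physical sample points.
make_velocity_sampler <- function(uc, wc, mapping) {
  N_i <- mapping$N_i; N_k <- mapping$N_k; N_kg <- mapping$N_kg
  dx <- mapping$dx
  hg <- mapping$hg; h <- mapping$h
  sample_one_col <- NULL # columns differ; use gather approach below
  function(X, Z) {
    dm <- dim(X)
    fx <- X / dx + 0.5                   # fractional column index
    i0 <- pmin(pmax(floor(fx), 1L), N_i - 1L)
    tx <- pmin(pmax(fx - i0, 0), 1)
    val <- function(F, icol) {
      # linear in z within column icol (matrix of column indices)
      hgc <- matrix(hg[icol], dm[1L]); hc <- matrix(h[icol], dm[1L])
      fi <- frac_center_index(Z, hgc, hc, N_kg, N_k)
      # bed anchor: below the first center interpolate towards 0 at z = 0
      below <- fi < 1
      fi_b <- pmin(pmax(fi, 1), N_k)
      k0 <- pmin(floor(fi_b), N_k - 1L)
      tz <- pmin(pmax(fi_b - k0, 0), 1)
      idx0 <- cbind(as.vector(icol), as.vector(k0))
      idx1 <- cbind(as.vector(icol), as.vector(k0) + 1L)
      v <- (1 - tz) * matrix(F[idx0], dm[1L]) + tz * matrix(F[idx1], dm[1L])
      if (any(below)) {
        v1 <- matrix(F[cbind(as.vector(icol), 1L)], dm[1L])
        zc1 <- 0.5 * hgc / N_kg
        vb <- v1 * pmax(Z, 0) / zc1
        v[below] <- vb[below]
      }
      v
    }
    u <- (1 - tx) * val(uc, i0) + tx * val(uc, i0 + 1L)
    w <- (1 - tx) * val(wc, i0) + tx * val(wc, i0 + 1L)
    list(u = u, w = w)
  }
}
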