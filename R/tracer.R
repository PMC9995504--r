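# Passive tracer: initialization, monotone conservative advection, vertical
# flux and canopy exchange.
#
# The reference distribution C0(z) = 2 (h_bar_g - z) is positive inside the
# grass bed, zero at the steady canopy top and negative in the overflow, so
# the vertical flux phi = w C' (C' = C - C0) measures material exchanged
# across the canopy interface.

#' Reference tracer profile
#' @param h_bar_g steady canopy-top height
#' @param z heights (vector or matrix)
#' @return `2 * (h_bar_g - z)`, same shape as `z`
#' @export
tracer_reference <- function(h_bar_g, z) 2 * (h_bar_g - z)

#' Initialize the tracer field on a mapping
#' @param h_bar_g steady canopy-top height
#' @param mapping a `monami_mapping`
#' @return `N_i x N_k` concentration matrix `C(i,k) = 2 (h_bar_g - z_c)`
#' @export
init_tracer <- function(h_bar_g, mapping) {
  tracer_reference(h_bar_g, mapping$z_c)
}

# van Leer slope-limited face value for donor cell with neighbours:
# cU (upwind-of-donor), cD (donor), cC (downwind); nu = local Courant.
muscl_face <- function(cU, cD, cC, nu) {
  num <- cD - cU
  den <- cC - cD
  r <- num / (den + (den == 0) * 1e-300)
  psi <- (r + abs(r)) / (1 + abs(r))
  cD + 0.5 * psi * den * (1 - nu)
}

#' Advect the tracer with a monotone flux-limited scheme
#'
#' Conservative flux-form advection on the mapped grid using the
#' contravariant volume fluxes of the (divergence-free) velocity field, with
#' van Leer slope limiting, forward Euler in time. Inlet Dirichlet to the
#' reference profile, outflow zero-gradient at the outlet, no flux through
#' the bed; the surface face carries the free-surface volume flux with the
#' donor (top cell) concentration.
#'
#' @param C `N_i x N_k` concentration field
#' @param fl contravariant flux set (`Qx`, `Qz`) as built inside the solver
#' @param geom solver geometry for the current mapping
#' @param mapping current `monami_mapping`
#' @param params a [sim_params()] object
#' @param c0_inlet inlet concentration profile (length `N_k`); defaults to
#'   zero-gradient if `NULL`
#' @return the advected concentration field
#' @export
advect_tracer <- function(C, fl, geom, mapping, params, c0_inlet = NULL) {
  N_i <- mapping$N_i; N_k <- mapping$N_k
  dx <- mapping$dx; dt <- params$dt
  # --- x fluxes at faces 1..N_i+1 ---
  Cg_in <- if (is.null(c0_inlet)) C[1L, ] else c0_inlet
  Cx <- rbind(Cg_in, Cg_in, C, C[N_i, ], C[N_i, ],
              deparse.level = 0)                     # padded (N_i+4) x N_k
  # face j (between padded cells j+1, j+2), j = 1..N_i+1
  Qx <- fl$Qx
  pos <- (Qx >= 0) + 0
  neg <- 1 - pos
  jj <- seq_len(N_i + 1L)
  cU <- pos * Cx[jj, , drop = FALSE] + neg * Cx[jj + 3L, , drop = FALSE]
  cD <- pos * Cx[jj + 1L, , drop = FALSE] + neg * Cx[jj + 2L, , drop = FALSE]
  cC <- pos * Cx[jj + 2L, , drop = FALSE] + neg * Cx[jj + 1L, , drop = FALSE]
  nux <- abs(Qx) * dt / (dx * geom$dzf_u)
  Fx <- Qx * muscl_face(cU, cD, cC, pmin(nux, 1))
  # --- z fluxes at sigma-faces 1..N_k+1 ---
  Qz <- fl$Qz
  Cz <- cbind(C[, 1L], C[, 1L], C, C[, N_k], C[, N_k])
  kk <- seq_len(N_k + 1L)
  posz <- (Qz >= 0) + 0
  negz <- 1 - posz
  cUz <- posz * Cz[, kk, drop = FALSE] + negz * Cz[, kk + 3L, drop = FALSE]
  cDz <- posz * Cz[, kk + 1L, drop = FALSE] +
    negz * Cz[, kk + 2L, drop = FALSE]
  cCz <- posz * Cz[, kk + 2L, drop = FALSE] +
    negz * Cz[, kk + 1L, drop = FALSE]
  dzfz <- cbind(mapping$dz[, 1L],
                0.5 * (mapping$dz[, -N_k, drop = FALSE] +
                         mapping$dz[, -1L, drop = FALSE]),
                mapping$dz[, N_k])
  nuz <- abs(Qz) * dt / (dx * dzfz)
  Fz <- Qz * muscl_face(cUz, cDz, cCz, pmin(nuz, 1))
  Fz[, 1L] <- 0                              # no flux through the bed
  Fz[, N_k + 1L] <- Qz[, N_k + 1L] * C[, N_k]  # free-surface donor flux
  V <- dx * mapping$dz
  C - dt * ((Fx[-1L, , drop = FALSE] - Fx[-(N_i + 1L), , drop = FALSE]) +
              (Fz[, -1L, drop = FALSE] - Fz[, -(N_k + 1L), drop = FALSE])) / V
}

#' Pointwise vertical tracer flux
#'
#' `phi = w C'` with `C' = C - C0(z)` evaluated at cell centers.
#'
#' @param state a `monami_state`
#' @param h_bar_g steady canopy height defining `C0` (defaults to the
#'   state's steady profile)
#' @return `N_i x N_k` flux field
#' @export
vertical_flux <- function(state, h_bar_g = state$steady$h_bar_g) {
  N_k <- state$mapping$N_k
  wc <- 0.5 * (state$w[, -(N_k + 1L), drop = FALSE] +
                 state$w[, -1L, drop = FALSE])
  Cp <- state$C - tracer_reference(h_bar_g, state$mapping$z_c)
  wc * Cp
}

#' Canopy-top tracer exchange integral
#'
#' `Phi = int_{x_a}^{x_b} |phi(x, z = h_bar_g)| dx`: `phi` is interpolated
#' linearly in z to the fixed steady canopy-top level in every column and
#' its absolute value integrated over x by the trapezoid rule.
#'
#' @param phi `N_i x N_k` vertical-flux field on `mapping` cell centers
#' @param mapping a `monami_mapping`
#' @param x_a,x_b along-channel integration window
#' @param h_bar_g the fixed evaluation level
#' @return the scalar exchange `Phi >= 0`
#' @export
exchange <- function(phi, mapping, x_a, x_b, h_bar_g) {
  N_i <- mapping$N_i; N_k <- mapping$N_k
  zq <- matrix(h_bar_g, N_i, 1L)
  fi <- frac_center_index(zq, matrix(mapping$hg, N_i), matrix(mapping$h, N_i),
                          mapping$N_kg, N_k)
  fi <- pmin(pmax(fi, 1), N_k)
  k0 <- pmin(floor(fi), N_k - 1L)
  tz <- fi - k0
  phl <- phi[cbind(seq_len(N_i), as.integer(k0))]
  phh <- phi[cbind(seq_len(N_i), as.integer(k0) + 1L)]
  line <- abs((1 - tz) * phl + tz * phh)
  xs <- (seq_len(N_i) - 0.5) * mapping$dx
  inside <- xs > x_a & xs < x_b
  xi <- c(x_a, xs[inside], x_b)
  yi <- c(stats::approx(xs, line, x_a, rule = 2)$y, line[inside],
          stats::approx(xs, line, x_b, rule = 2)$y)
  if (length(xi) < 2L) return(0)
  sum(0.5 * diff(xi) * (yi[-1L] + yi[-length(yi)]))
}
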