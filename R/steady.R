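# The x- and t-independent coupled base state: velocity profile u_bar(z),
# blade shape / angle, canopy height h_bar_g, and the constant horizontal
# forcing G tuned so that u_bar = 1 at the surface. The 1D problem reuses the
# 2D model's vertical grid, derivative stencils, velocity sampler and blade
# force deposition, so the returned profile is a discrete steady state of the
# channel solver.

# Internal width of the surrogate column block: the 1D state is represented
# as a few identical columns so that the (x-kernel) drag deposition and the
# bilinear sampler can be reused verbatim; the middle column is the profile.
STEADY_NCOL <- 9L

steady_block_params <- function(params) {
  p1 <- params
  p1$N_i <- STEADY_NCOL
  p1$L_r <- STEADY_NCOL * params$dx
  p1$L <- p1$L_r / 2
  p1
}

# Surface value of a profile with du/dz = 0 at z = h: value at h of the
# parabola through the two top cells with zero slope at h.
surface_value <- function(u, zc, h) {
  N_k <- length(u)
  a <- zc[N_k - 1L] - h
  b <- zc[N_k] - h
  A <- (u[N_k - 1L] - u[N_k]) / (a^2 - b^2)
  u[N_k] - A * b^2
}

#' Pointwise 1D steady momentum residual
#'
#' `residual(z) = (1/Re) d2u/dz2 + G - 1[z <= h_bar_g] lambda sec(theta)
#' f_x(u, theta)` with `f_x = u^2 cos^3(theta) / 2` (normal-velocity drag of
#' purely horizontal flow), discretized with the same second-order stencils
#' as the channel solver (no-slip bed, zero shear at the surface).
#'
#' @param u_profile velocity at the column cell centers
#' @param theta_profile blade angle mapped to the cell centers (0 above the
#'   canopy)
#' @param G constant forcing
#' @param params a [sim_params()] object
#' @param h_bar_g canopy-top height (defaults to the canopy interface
#'   implied by `params$r`)
#' @param h free-surface height
#' @return residual at each cell center
#' @export
steady_momentum_residual <- function(u_profile, theta_profile, G, params,
                                     h_bar_g = params$r, h = 1) {
  zc <- column_z_centers(h_bar_g, h, params)
  cf <- make_dz_coefs(matrix(zc, 1L), h, 2L, "dirichlet0", "neumann0")
  d2 <- as.numeric(apply_dz(cf, matrix(u_profile, 1L)))
  fx <- 0.5 * u_profile^2 * cos(theta_profile)^3
  mask <- as.numeric(zc <= h_bar_g)
  d2 / params$Re + G - mask * params$lam / cos(theta_profile) * fx
}

# Cell-center heights of a single column.
column_z_centers <- function(h_g, h, params) {
  N_k <- params$N_k; N_kg <- params$N_kg
  dzc <- h_g / N_kg
  dzo <- (h - h_g) / (N_k - N_kg)
  zf <- c(seq(0, h_g, length.out = N_kg + 1L),
          h_g + seq_len(N_k - N_kg) * dzo)
  0.5 * (zf[-1L] + zf[-length(zf)])
}

#' Solve the coupled 1D steady state
#'
#' Alternating iteration: (i) given the blade-drag profile, solve the
#' vertical momentum two-point boundary-value problem for `u_bar` with the
#' quadratic drag quasi-linearized about the previous iterate (the forcing
#' `G` then follows exactly from linearity by requiring `u_bar = 1` at the
#' surface); (ii) equilibrate the blade representative against `u_bar` and
#' rebuild the canopy height from its tip; (iii) rebuild the vertical grid
#' and re-deposit the blade forces. Iterated to joint convergence of
#' `u_bar`, `theta` and `h_bar_g`.
#'
#' @param params a [sim_params()] object
#' @param tol joint convergence tolerance on the largest change in `u_bar`,
#'   `theta` and `h_bar_g`
#' @param max_iter iteration cap
#' @param relax_u under-relaxation of the velocity update
#' @return object of class `monami_steady`: `z_levels`, `u_bar`,
#'   `theta_bar` (0 above the canopy), `blade` (a `monami_blade`),
#'   `h_bar_g`, `forcing_G`, `iterations`, `params`, and `drag_profile`
#'   (the deposited per-cell horizontal drag force per unit volume)
#' @export
solve_steady <- function(params, tol = 1e-10, max_iter = 400L,
                         relax_u = 0.7) {
  p1 <- steady_block_params(params)
  p1$blade_max_iter <- max(p1$blade_max_iter, 1000L)
  N_k <- p1$N_k
  nn <- p1$blade_nseg + 1L
  mid <- (STEADY_NCOL + 1L) %/% 2L
  h_g <- params$r
  theta <- matrix(0, STEADY_NCOL, nn)
  # drag-free start
  zc <- column_z_centers(h_g, 1, p1)
  u <- zc * (2 - zc)
  G <- 2 / params$Re
  dragx <- numeric(N_k)
  hist <- numeric(0)
  blades <- NULL
  for (it in seq_len(max_iter)) {
    zc <- column_z_centers(h_g, 1, p1)
    cf <- make_dz_coefs(matrix(zc, 1L), 1, 2L, "dirichlet0", "neumann0")
    # quasi-linearized BVP: (1/Re) D2 u - q u = -G, q = -drag/u_old >= 0
    q <- ifelse(abs(u) > 1e-12, pmax(0, -dragx / u), 0)
    # tridiagonal assemble (single column)
    lo <- as.numeric(cf$lo) / params$Re
    di <- as.numeric(cf$di) / params$Re - q
    up <- as.numeric(cf$up) / params$Re
    v <- thomas_solve(lo, di, up, rep(-1, N_k))   # u = G * v
    G_new <- 1 / surface_value(v, zc, 1)
    u_new <- G_new * v
    du <- max(abs(u_new - u))
    u <- (1 - relax_u) * u + relax_u * u_new
    G <- (1 - relax_u) * G + relax_u * G_new
    # blade equilibration against u on the current grid
    mapping <- build_mapping(rep(h_g, STEADY_NCOL), rep(1, STEADY_NCOL), p1)
    uc <- matrix(u, STEADY_NCOL, N_k, byrow = TRUE)
    wc <- matrix(0, STEADY_NCOL, N_k)
    can <- equilibrate_canopy(uc, wc, mapping, p1, theta0 = theta,
                              tol = min(tol * 0.1, 1e-11))
    dth <- max(abs(can$blades$theta - theta))
    theta <- can$blades$theta
    h_g_new <- can$h_g[mid]
    dhg <- abs(h_g_new - h_g)
    h_g <- h_g_new
    drag <- distribute_drag(can$blades, build_mapping(can$h_g, rep(1, STEADY_NCOL), p1), p1)
    dragx <- drag$Fx[mid, ]
    blades <- can$blades
    hist <- c(hist, max(du, dth, dhg))
    if (max(du, dth, dhg) < tol) {
      return(steady_result(params, p1, zc, u, theta[mid, ], h_g, G, it,
                           dragx, blades, mid))
    }
  }
  stop(sprintf(
    "steady-state iteration did not converge in %d iterations (last residual %.3e)",
    max_iter, hist[length(hist)]), call. = FALSE)
}

steady_result <- function(params, p1, zc, u, theta_s, h_g, G, it, dragx,
                          blades, mid) {
  # map theta(s) -> theta_bar(z) through z_g(s) (strictly increasing)
  zg <- blades$z_g[mid, ]
  th <- blades$theta[mid, ]
  inside <- zc <= h_g
  theta_bar <- numeric(length(zc))
  if (any(inside)) {
    theta_bar[inside] <- interp_mono_rows(matrix(zg, 1L), matrix(th, 1L),
                                          matrix(zc[inside], 1L))[1L, ]
  }
  nn <- length(th)
  blade <- structure(list(root_x = 0,
                          s_grid = blade_s_nodes(params$r, nn - 1L),
                          theta = th,
                          coords = cbind(x_g = blades$x_g[mid, ],
                                         z_g = zg),
                          tension = cbind(Tx = blades$Tx[mid, ],
                                          Tz = blades$Tz[mid, ]),
                          tip_height = zg[nn],
                          iterations = blades$iterations,
                          residual = blades$residual),
                     class = "monami_blade")
  structure(list(z_levels = zc, u_bar = u, theta_bar = theta_bar,
                 blade = blade, h_bar_g = h_g, forcing_G = G,
                 iterations = it, drag_profile = dragx,
                 theta_nodes = th, params = params),
            class = "monami_steady")
}

#' @exportS3Method base::print
print.monami_steady <- function(x, ...) {
  cat("steady canopy-channel base state\n")
  cat(sprintf("  Re = %g, beta = %g, lambda = %g, r = %g\n",
              x$params$Re, x$params$beta, x$params$lam, x$params$r))
  cat(sprintf("  h_bar_g = %.6f, G = %.6g, converged in %d iterations\n",
              x$h_bar_g, x$forcing_G, x$iterations))
  cat(sprintf("  canopy-top shear du/dz = %.4f\n", canopy_top_shear(x)))
  invisible(x)
}

#' @export
plot.monami_steady <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  plot(x$u_bar, x$z_levels, type = "l", xlab = "u", ylab = "z",
       main = "velocity", ...)
  graphics::abline(h = x$h_bar_g, lty = 2)
  plot(x$theta_bar, x$z_levels, type = "l", xlab = "theta", ylab = "z",
       main = "blade angle", ...)
  plot(x$blade$coords[, "x_g"], x$blade$coords[, "z_g"], type = "l",
       asp = 1, xlab = "x_g", ylab = "z_g", main = "blade shape", ...)
  invisible(x)
}

#' Velocity shear at the canopy top of a steady profile
#' @param profile a `monami_steady` object
#' @return `du/dz` evaluated at `z = h_bar_g`
#' @export
canopy_top_shear <- function(profile) {
  zc <- profile$z_levels
  u <- profile$u_bar
  k <- findInterval(profile$h_bar_g, zc)
  k <- min(max(k, 2L), length(zc) - 1L)
  w <- lagrange3_weights(zc[k - 1L], zc[k], zc[k + 1L], profile$h_bar_g, 1L)
  w$w0 * u[k - 1L] + w$w1 * u[k] + w$w2 * u[k + 1L]
}

#' Interpolator for a steady profile
#'
#' Returns a vectorised function `u(z)` built from the monotone-cubic
#' interpolant of the steady velocity through the cell centers, anchored at
#' the no-slip bed and extended with zero slope above the top cell.
#' @param profile a `monami_steady` object
#' @return function of `z`
#' @export
steady_velocity_fun <- function(profile) {
  zc <- c(0, profile$z_levels)
  uu <- c(0, profile$u_bar)
  sf <- stats::splinefun(zc, uu, method = "monoH.FC")
  ztop <- zc[length(zc)]
  function(z) {
    out <- sf(pmin(pmax(z, 0), ztop))
    dim(out) <- dim(z)
    out
  }
}
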