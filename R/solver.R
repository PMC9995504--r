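# Time integration of the dimensionless incompressible momentum equations
# with free surface, homogenized canopy drag, sponge and tracer, on the
# deforming terrain-following grid.
#
# Staggered (MAC) layout: u at x-faces ((N_i+1) x N_k, rows 1 and N_i+1 are
# the Dirichlet inlet/outlet), w at sigma-faces (N_i x (N_k+1), bed face
# zero, surface face kinematic), p and C at cell centers. One step:
#   (1) blade equilibration + drag assembly from the pre-step velocities;
#   (2) explicit AB3 predictor (advection, horizontal viscosity, drag,
#       forcing G) followed by implicit (backward Euler) vertical viscosity;
#   (3) semi-implicit theta-scheme free-surface update (tridiagonal in x);
#   (4) nonhydrostatic pressure projection (p = 0 at the surface);
#   (5) sponge restoring towards the steady profile in the outflow buffer;
#   (6) monotone (van Leer) conservative tracer advection;
#   (7) re-map all fields to the updated (h_g, h) grid.

# Geometry helpers reused across the step -----------------------------------

solver_geometry <- function(mapping) {
  N_i <- mapping$N_i; N_k <- mapping$N_k
  dz <- mapping$dz
  # x-face column layer heights and center heights (boundary faces copy the
  # adjacent column)
  dzf_u <- rbind(dz[1L, ], 0.5 * (dz[-N_i, ] + dz[-1L, ]), dz[N_i, ])
  z_u <- rbind(mapping$z_c[1L, ],
               0.5 * (mapping$z_c[-N_i, ] + mapping$z_c[-1L, ]),
               mapping$z_c[N_i, ])
  h_u <- c(mapping$h[1L], 0.5 * (mapping$h[-N_i] + mapping$h[-1L]),
           mapping$h[N_i])
  zxf_w <- ddx_matrix(mapping$z_f, mapping$dx)   # dz/dx at sigma-faces
  list(dz = dz, dzf_u = dzf_u, z_u = z_u, h_u = h_u, zxf_w = zxf_w,
       dzz = mapping$z_c[, -1L, drop = FALSE] -
         mapping$z_c[, -N_k, drop = FALSE],      # center-to-center spacing
       dz_top2 = mapping$z_f[, N_k + 1L] - mapping$z_c[, N_k])
}

# Contravariant volume fluxes from (u, w) on the current grid.
state_fluxes <- function(u, w, geom, mapping) {
  N_i <- mapping$N_i; N_k <- mapping$N_k
  Qx <- u * geom$dzf_u
  # u interpolated to sigma-faces (interior faces; bed/top rows via copy)
  uc <- 0.5 * (u[-(N_i + 1L), , drop = FALSE] + u[-1L, , drop = FALSE])
  uz <- cbind(uc[, 1L], 0.5 * (uc[, -N_k, drop = FALSE] +
                                 uc[, -1L, drop = FALSE]), uc[, N_k])
  Qz <- mapping$dx * (w - uz * geom$zxf_w)
  Qz[, 1L] <- 0
  list(Qx = Qx, Qz = Qz, uz = uz)
}

# Cell-integrated divergence (volume flux imbalance) of a flux set.
flux_divergence <- function(fl, N_i) {
  (fl$Qx[-1L, , drop = FALSE] - fl$Qx[-(N_i + 1L), , drop = FALSE]) +
    (fl$Qz[, -1L, drop = FALSE] - fl$Qz[, -ncol(fl$Qz), drop = FALSE])
}

#' Initialize the channel state from a steady profile
#'
#' Velocities are set to the steady profile (`u(i,k) = u_bar(z)`, `w = 0`)
#' plus seeded uniform white noise of amplitude `noise_amplitude` on the
#' interior vertical velocity (the deterministic trigger of the shear-layer
#' instability), the free surface to 1, the canopy to the steady height with
#' blades at the steady shape, and the tracer to the linear reference
#' profile `C0(z) = 2 (h_bar_g - z)`.
#'
#' @param params a [sim_params()] object
#' @param steady_profile a [solve_steady()] result for the same parameters
#' @return an object of class `monami_state`
#' @export
initialize_state <- function(params, steady_profile) {
  N_i <- params$N_i; N_k <- params$N_k
  if (length(steady_profile$u_bar) != N_k)
    stop("steady profile has inconsistent grid dimensions", call. = FALSE)
  hg <- rep(steady_profile$h_bar_g, N_i)
  h <- rep(1, N_i)
  mapping <- build_mapping(hg, h, params)
  ubar_fun <- steady_velocity_fun(steady_profile)
  geom <- solver_geometry(mapping)
  u <- ubar_fun(geom$z_u)
  w <- matrix(0, N_i, N_k + 1L)
  if (params$noise_amplitude > 0) {
    rs <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(params$rng_seed)
    w[, 2:N_k] <- matrix(stats::runif(N_i * (N_k - 1L),
                                      -params$noise_amplitude,
                                      params$noise_amplitude), N_i)
    if (!is.null(rs)) assign(".Random.seed", rs, globalenv())
  }
  # blades at the steady shape in every column
  theta <- matrix(steady_profile$theta_nodes, N_i,
                  params$blade_nseg + 1L, byrow = TRUE)
  C <- init_tracer(steady_profile$h_bar_g, mapping)
  structure(list(t = 0, nstep = 0L,
                 u = u, w = w, C = C, h = h, hg = hg,
                 p = matrix(0, N_i, N_k),
                 mapping = mapping,
                 blades_theta = theta, blades = NULL,
                 drag = NULL,
                 prev_tend = NULL,
                 steady = steady_profile,
                 ubar_fun = ubar_fun,
                 params = params,
                 poisson = NULL,
                 last_divergence = NA_real_,
                 blade_iters = NA_integer_,
                 log = list()),
            class = "monami_state")
}

#' @exportS3Method base::print
print.monami_state <- function(x, ...) {
  cat(sprintf(
    "channel state at t = %.2f: h_g in [%.4f, %.4f], max |w| = %.3g, divergence %.2g\n",
    x$t, min(x$hg), max(x$hg), max(abs(x$w)), x$last_divergence))
  invisible(x)
}

# Sponge restoring weights at x positions xs (0 at x = L, ramping to
# sponge_rate at x = L_r by a half-cosine).
sponge_weights <- function(xs, params) {
  s <- (xs - params$L) / (params$L_r - params$L)
  s <- pmin(pmax(s, 0), 1)
  params$sponge_rate * 0.5 * (1 - cos(pi * s))
}

#' Apply the outflow-buffer restoring to a state
#'
#' `u <- u - dt sigma_r(x) (u - u_bar)`, `w <- w - dt sigma_r(x) w`, with
#' `sigma_r` ramping as a half-cosine from 0 at `x = L` to `sponge_rate` at
#' `x = L_r`.
#'
#' @param state a `monami_state`
#' @param params a [sim_params()] object
#' @return the state with damped buffer velocities
#' @export
apply_sponge <- function(state, params = state$params) {
  geom <- solver_geometry(state$mapping)
  xf <- (seq_len(params$N_i + 1L) - 1L) * params$dx
  wt_f <- pmin(sponge_weights(xf, params) * params$dt, 1)
  act <- which(wt_f > 0)
  if (length(act)) {
    ub <- state$ubar_fun(geom$z_u[act, , drop = FALSE])
    state$u[act, ] <- state$u[act, , drop = FALSE] -
      wt_f[act] * (state$u[act, , drop = FALSE] - ub)
  }
  wt_c <- pmin(sponge_weights(x_centers(params), params) * params$dt, 1)
  actc <- which(wt_c > 0)
  if (length(actc))
    state$w[actc, ] <- (1 - wt_c[actc]) * state$w[actc, , drop = FALSE]
  state
}

# Momentum advection tendencies (conservative flux form, centered with an
# optional upwind blend), returned at interior u-faces / interior w-faces.
advect_momentum <- function(u, w, fl, geom, params) {
  N_i <- params$N_i; N_k <- params$N_k
  dx <- params$dx
  blend <- params$upwind_blend
  cface <- function(qL, qR, Q) {
    v <- 0.5 * (qL + qR)
    if (blend > 0) v <- v - blend * 0.5 * sign(Q) * (qR - qL)
    v
  }
  # --- u equation (dual cells centered on x-faces) ---
  # x-fluxes through cell centers: mean of adjacent face fluxes
  Qxc <- 0.5 * (fl$Qx[-(N_i + 1L), , drop = FALSE] + fl$Qx[-1L, , drop = FALSE])
  uce <- cface(u[-(N_i + 1L), , drop = FALSE], u[-1L, , drop = FALSE], Qxc)
  FUx <- Qxc * uce                                  # N_i x N_k
  # z-fluxes through u-cell corners: mean of adjacent column Qz
  Qzu <- 0.5 * (fl$Qz[-N_i, , drop = FALSE] + fl$Qz[-1L, , drop = FALSE])
  # corner u values: average in k (bed no-slip, top one-sided)
  u_int <- u[2:N_i, , drop = FALSE]
  u_lo <- cbind(u_int[, 1L] * 0,
                cface(u_int[, -N_k, drop = FALSE],
                      u_int[, -1L, drop = FALSE],
                      Qzu[, 2:N_k, drop = FALSE]),
                u_int[, N_k])
  u_lo[, 1L] <- 0                                   # no-slip bed
  FUz <- Qzu * u_lo                                 # (N_i-1) x (N_k+1)
  Vu <- dx * geom$dzf_u[2:N_i, , drop = FALSE]
  adv_u <- (FUx[-1L, , drop = FALSE] - FUx[-N_i, , drop = FALSE] +
              FUz[, -1L, drop = FALSE] - FUz[, -(N_k + 1L), drop = FALSE]) / Vu
  # --- w equation (dual cells centered on sigma-faces k = 2..N_k) ---
  kk <- 2:N_k
  # x-fluxes through w-cell vertical faces: mean of Qx over the two layers
  Qxw <- 0.5 * (fl$Qx[, kk - 1L, drop = FALSE] + fl$Qx[, kk, drop = FALSE])
  # face w values between columns (0 at the channel ends)
  wL <- rbind(0, cface(w[-N_i, kk, drop = FALSE], w[-1L, kk, drop = FALSE],
                       Qxw[2:N_i, , drop = FALSE]), 0)
  FWx <- Qxw * wL                                   # (N_i+1) x (N_k-1)
  # z-fluxes through w-cell centers (cell centers k-1 and k bracket face k)
  Qzw <- 0.5 * (fl$Qz[, kk - 1L, drop = FALSE] + fl$Qz[, kk, drop = FALSE])
  # value of w at cell centers: mean of bracketing faces (optional blend)
  Qz_at_c <- 0.5 * (fl$Qz[, -(N_k + 1L), drop = FALSE] +
                      fl$Qz[, -1L, drop = FALSE])
  w_at_c <- cface(w[, -(N_k + 1L), drop = FALSE], w[, -1L, drop = FALSE],
                  Qz_at_c)
  FWz_lo <- Qzw * w_at_c[, kk - 1L, drop = FALSE]
  FWz_hi <- 0.5 * (fl$Qz[, kk, drop = FALSE] +
                     fl$Qz[, kk + 1L, drop = FALSE]) *
    w_at_c[, kk, drop = FALSE]
  Vw <- dx * geom$dzz
  adv_w <- (FWx[-1L, , drop = FALSE] - FWx[-(N_i + 1L), , drop = FALSE] +
              FWz_hi - FWz_lo) / Vw
  list(adv_u = adv_u, adv_w = adv_w)
}

# One full time step. Returns the updated state.
#' Advance the channel state by one time step
#' @param state a `monami_state`
#' @param params a [sim_params()] object (defaults to the state's)
#' @return the advanced state
#' @export
step_flow <- function(state, params = state$params) {
  N_i <- params$N_i; N_k <- params$N_k
  dx <- params$dx; dt <- params$dt
  mapping <- state$mapping
  geom <- solver_geometry(mapping)
  u <- state$u; w <- state$w
  # CFL guard (pointwise vertical Courant)
  N_kv <- N_k
  dz_w <- pmin(mapping$dz[, -N_kv, drop = FALSE],
               mapping$dz[, -1L, drop = FALSE])
  cfl <- max(max(abs(u)) * dt / dx,
             max(abs(w[, 2:N_kv, drop = FALSE]) / dz_w) * dt)
  if (!is.finite(cfl) || cfl > params$cfl_max)
    stop(sprintf("CFL violation at t = %.2f (CFL = %.3f)", state$t, cfl),
         call. = FALSE)
  # (1) blade equilibration and drag assembly from pre-step velocities
  uc <- 0.5 * (u[-(N_i + 1L), , drop = FALSE] + u[-1L, , drop = FALSE])
  wc <- 0.5 * (w[, -(N_k + 1L), drop = FALSE] + w[, -1L, drop = FALSE])
  th_warm <- state$blades_theta
  if (!is.null(state$blades_theta_prev))
    th_warm <- pmin(pmax(2 * state$blades_theta - state$blades_theta_prev,
                         -1.55), 1.55)
  cpl <- couple_step(uc, wc, mapping, params, theta0 = th_warm)
  hg_new <- cpl$h_g
  # (2) predictor tendencies
  fl <- state_fluxes(u, w, geom, mapping)
  adv <- advect_momentum(u, w, fl, geom, params)
  # horizontal viscosity is explicit; vertical viscosity is applied
  # implicitly after the predictor (the bed-adjacent vertical diffusion
  # number nu dt/dz^2 lies outside any explicit multistep stability region)
  visc_u <- matrix(0, N_i + 1L, N_k)
  visc_u[2:N_i, ] <- (u[1:(N_i - 1L), , drop = FALSE] -
                        2 * u[2:N_i, , drop = FALSE] +
                        u[3:(N_i + 1L), , drop = FALSE]) / dx^2
  wgl <- rbind(-w[1L, , drop = FALSE], w[-N_i, , drop = FALSE])
  wgr <- rbind(w[-1L, , drop = FALSE], -w[N_i, , drop = FALSE])
  visc_w <- (wgl - 2 * w + wgr) / dx^2
  # drag to faces
  Fx <- cpl$drag$Fx; Fz <- cpl$drag$Fz
  Fx_u <- rbind(Fx[1L, ], 0.5 * (Fx[-N_i, , drop = FALSE] +
                                   Fx[-1L, , drop = FALSE]), Fx[N_i, ])
  Fz_w <- cbind(rep(0, N_i),
                0.5 * (Fz[, -N_k, drop = FALSE] + Fz[, -1L, drop = FALSE]),
                rep(0, N_i))
  G <- state$steady$forcing_G
  tend_u <- matrix(0, N_i + 1L, N_k)
  tend_u[2:N_i, ] <- -adv$adv_u +
    visc_u[2:N_i, , drop = FALSE] / params$Re +
    Fx_u[2:N_i, , drop = FALSE] + G
  tend_w <- matrix(0, N_i, N_k + 1L)
  tend_w[, 2:N_k] <- -adv$adv_w +
    visc_w[, 2:N_k, drop = FALSE] / params$Re +
    Fz_w[, 2:N_k, drop = FALSE]
  if (is.null(state$prev_tend)) {
    du <- tend_u; dw <- tend_w               # Euler on the first step
  } else if (is.null(state$prev2_tend)) {
    du <- 1.5 * tend_u - 0.5 * state$prev_tend$u
    dw <- 1.5 * tend_w - 0.5 * state$prev_tend$w
  } else {
    du <- (23 * tend_u - 16 * state$prev_tend$u +
             5 * state$prev2_tend$u) / 12
    dw <- (23 * tend_w - 16 * state$prev_tend$w +
             5 * state$prev2_tend$w) / 12
  }
  us <- u + dt * du
  ws <- w + dt * dw
  # implicit (backward Euler) vertical viscosity: preserves the discrete
  # steady balance exactly and is unconditionally stable
  al <- dt / params$Re
  cf_u <- make_dz_coefs(geom$z_u, geom$h_u, 2L, "dirichlet0", "neumann0")
  ui <- thomas_solve_rows(-al * cf_u$lo, 1 - al * cf_u$di, -al * cf_u$up, us)
  if (isTRUE(params$collect_budget))
    visc_z_int <- sum((ui[2:N_i, , drop = FALSE] -
                         us[2:N_i, , drop = FALSE]) *
                        dx * geom$dzf_u[2:N_i, , drop = FALSE])
  ui[1L, ] <- us[1L, ]; ui[N_i + 1L, ] <- us[N_i + 1L, ]
  us <- ui
  cf_w <- make_dz_coefs(mapping$z_f, mapping$h, 2L, "onesided", "onesided")
  kk <- 2:N_k
  rhs_w <- ws[, kk, drop = FALSE]
  rhs_w[, N_k - 1L] <- rhs_w[, N_k - 1L] +
    al * cf_w$up[, N_k] * ws[, N_k + 1L]
  ws[, kk] <- thomas_solve_rows(-al * cf_w$lo[, kk, drop = FALSE],
                                1 - al * cf_w$di[, kk, drop = FALSE],
                                -al * cf_w$up[, kk, drop = FALSE], rhs_w)
  if (isTRUE(params$collect_budget)) {
    Vu <- dx * geom$dzf_u
    bsum <- function(M) sum(M[2:N_i, , drop = FALSE] *
                              Vu[2:N_i, , drop = FALSE])
    bud <- list(U0 = sum(u * Vu),
                pred = dt * bsum(du),
                visc_z = visc_z_int,
                adv = -dt * bsum(rbind(0, adv$adv_u, 0)),
                visc = dt * bsum(visc_u) / params$Re,
                drag = dt * bsum(Fx_u),
                forc = dt * G * sum(Vu[2:N_i, , drop = FALSE]))
  }
  # (3) semi-implicit free-surface update (theta scheme, tridiagonal in x)
  th <- params$theta_fs
  Qn <- rowSums(fl$Qx)                        # per x-face, length N_i+1
  Qs <- rowSums(us * geom$dzf_u)
  Df <- c(0, rowSums(geom$dzf_u)[2:N_i], 0)   # no slope correction at ends
  hn <- state$h
  cf2 <- (dt * th)^2 / (params$Fr2 * dx^2)
  cfn <- dt^2 * th * (1 - th) / (params$Fr2 * dx^2)
  dhn <- c(0, diff(hn))                       # at faces 1..N_i (+1 below)
  dhn_f <- c(dhn, 0)
  lapn <- Df[2:(N_i + 1L)] * dhn_f[2:(N_i + 1L)] -
    Df[1:N_i] * dhn_f[1:N_i]
  rhs <- hn - (dt / dx) * (th * diff(Qs) + (1 - th) * diff(Qn)) + cfn * lapn
  sub <- -cf2 * Df[1:N_i]
  sup <- -cf2 * Df[2:(N_i + 1L)]
  main <- 1 + cf2 * (Df[1:N_i] + Df[2:(N_i + 1L)])
  h_new <- thomas_solve(c(0, sub[-1L]), main, c(sup[-N_i], 0), rhs)
  dh_mix <- th * diff(h_new) + (1 - th) * diff(hn)
  us[2:N_i, ] <- us[2:N_i, , drop = FALSE] -
    (dt / (params$Fr2 * dx)) * dh_mix
  if (isTRUE(params$collect_budget))
    bud$slope <- -sum((dt / (params$Fr2 * dx)) * dh_mix *
                        dx * geom$dzf_u[2:N_i, , drop = FALSE])
  # (4) projection
  fls <- state_fluxes(us, ws, geom, mapping)
  fls$Qz[, N_k + 1L] <- dx * (h_new - hn) / dt   # kinematic top flux
  dv <- flux_divergence(fls, N_i)
  if (is.null(state$poisson)) state$poisson <- poisson_env(N_i, N_k)
  need_fact <- is.null(state$poisson$hg_fact) ||
    max(abs(state$poisson$hg_fact - mapping$hg)) > params$refactor_tol ||
    max(abs(state$poisson$h_fact - mapping$h)) > params$refactor_tol
  ax <- geom$dzf_u[2:N_i, , drop = FALSE] / dx
  az <- dx / geom$dzz
  az_top <- dx / geom$dz_top2
  poisson_assemble(state$poisson, ax, az, az_top, refactor = need_fact)
  if (need_fact) {
    state$poisson$hg_fact <- mapping$hg
    state$poisson$h_fact <- mapping$h
  }
  p <- poisson_solve(state$poisson, -as.numeric(dv) / dt,
                     tol = params$poisson_tol)
  p <- matrix(p, N_i, N_k)
  if (isTRUE(params$collect_budget))
    bud$proj <- -sum(dt * (p[-1L, , drop = FALSE] -
                             p[-N_i, , drop = FALSE]) / dx *
                       dx * geom$dzf_u[2:N_i, , drop = FALSE])
  us[2:N_i, ] <- us[2:N_i, , drop = FALSE] -
    dt * (p[-1L, , drop = FALSE] - p[-N_i, , drop = FALSE]) / dx
  dQz <- matrix(0, N_i, N_k + 1L)
  dQz[, 2:N_k] <- -dt * az * (p[, -1L, drop = FALSE] - p[, -N_k, drop = FALSE])
  dQz[, N_k + 1L] <- dt * az_top * p[, N_k]
  fls$Qz <- fls$Qz + dQz
  # recover w from corrected contravariant flux and corrected u
  flc <- state_fluxes(us, ws, geom, mapping)   # for updated uz only
  ws <- fls$Qz / dx + flc$uz * geom$zxf_w
  ws[, 1L] <- 0
  # divergence diagnostic (physical units: flux imbalance / cell volume)
  flv <- list(Qx = us * geom$dzf_u, Qz = fls$Qz)
  dvol <- flux_divergence(flv, N_i) / (dx * geom$dz)
  state$last_divergence <- max(abs(dvol))
  state$p <- p
  # (5) sponge
  xf <- (seq_len(N_i + 1L) - 1L) * dx
  wt_f <- pmin(sponge_weights(xf, params) * dt, 1)
  act <- which(wt_f > 0)
  if (isTRUE(params$collect_budget)) u_presponge <- us
  if (length(act)) {
    ub <- state$ubar_fun(geom$z_u[act, , drop = FALSE])
    us[act, ] <- us[act, , drop = FALSE] -
      wt_f[act] * (us[act, , drop = FALSE] - ub)
  }
  wt_c <- pmin(sponge_weights(x_centers(params), params) * dt, 1)
  actc <- which(wt_c > 0)
  if (length(actc))
    ws[actc, ] <- (1 - wt_c[actc]) * ws[actc, , drop = FALSE]
  if (isTRUE(params$collect_budget))
    bud$sponge <- sum((us - u_presponge) * dx * geom$dzf_u)
  # (6) tracer advection with the final velocities
  flt <- state_fluxes(us, ws, geom, mapping)
  flt$Qz[, N_k + 1L] <- fls$Qz[, N_k + 1L]
  C <- advect_tracer(state$C, flt, geom, mapping, params,
                     c0_inlet = tracer_reference(state$steady$h_bar_g,
                                                 mapping$z_c[1L, ]))
  # (7) re-map to the updated geometry
  new_mapping <- build_mapping(hg_new, h_new, params)
  geom_new <- solver_geometry(new_mapping)
  if (!identical(mapping$hg, hg_new) || !identical(mapping$h, h_new)) {
    N_kg <- params$N_kg
    hg_m <- matrix(mapping$hg, N_i, N_k)
    h_m <- matrix(mapping$h, N_i, N_k)
    hg_u <- matrix(c(mapping$hg[1L],
                     0.5 * (mapping$hg[-N_i] + mapping$hg[-1L]),
                     mapping$hg[N_i]), N_i + 1L, N_k)
    h_um <- matrix(geom$h_u, N_i + 1L, N_k)
    iu <- floor(frac_center_index(geom_new$z_u, hg_u, h_um, N_kg, N_k))
    iu <- pmin(pmax(iu, 1), N_k - 1L)
    u_new <- interp_mono_rows(geom$z_u, us, geom_new$z_u, iu)
    iw <- floor(frac_face_index(new_mapping$z_f,
                                matrix(mapping$hg, N_i, N_k + 1L),
                                matrix(mapping$h, N_i, N_k + 1L),
                                N_kg, N_k))
    iw <- pmin(pmax(iw, 1), N_k)
    w_new <- interp_mono_rows(mapping$z_f, ws, new_mapping$z_f, iw)
    ic <- floor(frac_center_index(new_mapping$z_c, hg_m, h_m, N_kg, N_k))
    ic <- pmin(pmax(ic, 1), N_k - 1L)
    C <- interp_mono_rows(mapping$z_c, C, new_mapping$z_c, ic)
  } else {
    u_new <- us; w_new <- ws
  }
  # boundary conditions on the new grid
  u_new[1L, ] <- state$ubar_fun(geom_new$z_u[1L, , drop = FALSE])
  u_new[N_i + 1L, ] <- state$ubar_fun(geom_new$z_u[N_i + 1L, , drop = FALSE])
  w_new[, 1L] <- 0
  if (isTRUE(params$collect_budget)) {
    bud$remap <- sum(u_new * dx * geom_new$dzf_u) - sum(us * dx * geom$dzf_u)
    bud$U1 <- sum(u_new * dx * geom_new$dzf_u)
    state$budget <- bud
  }
  state$u <- u_new
  state$w <- w_new
  state$C <- C
  state$h <- h_new
  state$hg <- hg_new
  state$mapping <- new_mapping
  state$blades <- cpl$blades
  state$blades_theta_prev <- state$blades_theta
  state$blades_theta <- cpl$blades$theta
  state$drag <- cpl$drag
  state$blade_iters <- cpl$blades$iterations
  state$prev2_tend <- state$prev_tend
  state$prev_tend <- list(u = tend_u, w = tend_w)
  state$t <- state$t + dt
  state$nstep <- state$nstep + 1L
  state
}

#' Vorticity field of a state
#'
#' `zeta = du/dz - dw/dx` at cell centers, with the metric-corrected
#' horizontal derivative and the nonuniform vertical stencils (exact on
#' quadratics; the no-slip bed value anchors the bottom stencil).
#'
#' @param state a `monami_state`
#' @return `N_i x N_k` matrix
#' @export
vorticity <- function(state) {
  mapping <- state$mapping
  N_i <- mapping$N_i; N_k <- mapping$N_k
  uc <- 0.5 * (state$u[-(N_i + 1L), , drop = FALSE] +
                 state$u[-1L, , drop = FALSE])
  wc <- 0.5 * (state$w[, -(N_k + 1L), drop = FALSE] +
                 state$w[, -1L, drop = FALSE])
  cf1u <- make_dz_coefs(mapping$z_c, mapping$h, 1L, "dirichlet0", "onesided")
  dudz <- apply_dz(cf1u, uc)
  cf1w <- make_dz_coefs(mapping$z_c, mapping$h, 1L, "dirichlet0", "onesided")
  dwdz <- apply_dz(cf1w, wc)
  dwdx <- ddx_matrix(wc, mapping$dx) - mapping$dzdx_c * dwdz
  dudz - dwdx
}
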