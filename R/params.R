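#' Simulation parameters
#'
#' Construct the full parameter set for a channel simulation. Defaults are the
#' baseline configuration: `Re = 1000`, `beta = 0.10`, `r = 0.5`, `lam = 1`,
#' `Fr2 = 0.1` on a 216 x 48 grid (`N_kg = 24` canopy layers), `dx = 0.2`,
#' `dt = 0.1`, analysis length `L = 36` inside a total channel `L_r = 43.2`
#' whose last section is a sponge (restoring buffer), run to `T_end = 500`.
#'
#' All quantities are dimensionless: lengths in units of the undisturbed water
#' depth H, velocities in units of the undisturbed surface speed U, time in
#' H/U.
#'
#' @param Re Reynolds number `U H / nu*` built on the (constant eddy)
#'   viscosity.
#' @param beta blade buoyancy parameter, ratio of blade buoyancy to drag;
#'   larger `beta` means stiffer-standing (less deflected) grass.
#' @param r undisturbed blade length relative to water depth (blade length
#'   `ell = r`).
#' @param lam bulk canopy drag density `c_D N b H`; scales the force on the
#'   fluid (not the blade deflection).
#' @param Fr2 squared Froude number `U^2/(g H)`; controls the free-surface
#'   stiffness.
#' @param N_i,N_k,N_kg number of columns, vertical layers, and canopy layers
#'   (layers `1..N_kg` span `[0, h_g]` in each column).
#' @param dx,dt horizontal grid spacing and time step.
#' @param L,L_r analysis length and total channel length; `x in [L, L_r]` is
#'   the sponge.
#' @param T_end run length.
#' @param x_a,x_b along-channel window for the tracer exchange integral.
#' @param t_avg_lo,t_avg_hi averaging window for long-term statistics.
#' @param noise_amplitude amplitude of the uniform white noise seeded on the
#'   initial vertical velocity (deterministic trigger for the instability).
#' @param rng_seed integer seed for the noise.
#' @param sponge_rate maximum restoring rate `sigma_max` of the sponge;
#'   `sigma_max * dt = 1` restores fully at the outlet.
#' @param output_cadence interval (time units) between diagnostic samples.
#' @param blade_nseg number of blade arc-length segments.
#' @param blade_tol,blade_relax,blade_max_iter controls for the blade
#'   under-relaxation fixed-point iteration.
#' @param theta_fs implicitness of the free-surface theta-scheme (> 0.5 for
#'   unconditional gravity-wave stability).
#' @param cfl_max advective CFL guard; the step aborts above it.
#' @param upwind_blend fraction of first-order upwind blended into the
#'   centered momentum advection (0 = pure centered).
#' @param refactor_tol grid deformation (max change in `h_g` or `h`) since the
#'   last Poisson factorisation that triggers a numeric refactorisation.
#' @param poisson_tol relative residual tolerance of the pressure solve.
#' @param sec_clamp clamp on the blade angle used in the `sec(theta)`
#'   homogenization factor (guards pathological transients).
#' @param snapshot_cadence interval between stored full-field snapshots
#'   (`Inf` stores only the final state).
#' @param collect_budget record the per-step domain-integrated x-momentum
#'   budget terms (diagnostic; small overhead).
#'
#' @return An object of class `monami_params` (a validated named list).
#' @export
sim_params <- function(Re = 1000, beta = 0.10, r = 0.5, lam = 1, Fr2 = 0.1,
                       N_i = 216L, N_k = 48L, N_kg = 24L,
                       dx = 0.2, dt = 0.1,
                       L = 36, L_r = 43.2, T_end = 500,
                       x_a = 20, x_b = 35,
                       t_avg_lo = 300, t_avg_hi = 500,
                       noise_amplitude = 1e-6, rng_seed = 0L,
                       sponge_rate = 10,
                       output_cadence = 1.0,
                       blade_nseg = 25L, blade_tol = 1e-6,
                       blade_relax = 0.5, blade_max_iter = 500L,
                       theta_fs = 0.55, cfl_max = 0.9, upwind_blend = 0,
                       refactor_tol = 1e-3, poisson_tol = 1e-9,
                       sec_clamp = 1.45, snapshot_cadence = Inf,
                       collect_budget = FALSE) {
  p <- list(Re = Re, beta = beta, r = r, lam = lam, Fr2 = Fr2,
            N_i = as.integer(N_i), N_k = as.integer(N_k),
            N_kg = as.integer(N_kg),
            dx = dx, dt = dt, L = L, L_r = L_r, T_end = T_end,
            x_a = x_a, x_b = x_b,
            t_avg_lo = t_avg_lo, t_avg_hi = t_avg_hi,
            noise_amplitude = noise_amplitude,
            rng_seed = as.integer(rng_seed),
            sponge_rate = sponge_rate,
            output_cadence = output_cadence,
            blade_nseg = as.integer(blade_nseg), blade_tol = blade_tol,
            blade_relax = blade_relax,
            blade_max_iter = as.integer(blade_max_iter),
            theta_fs = theta_fs, cfl_max = cfl_max,
            upwind_blend = upwind_blend,
            refactor_tol = refactor_tol, poisson_tol = poisson_tol,
            sec_clamp = sec_clamp, snapshot_cadence = snapshot_cadence,
            collect_budget = isTRUE(collect_budget))
  class(p) <- "monami_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid parameter: ", msg,
                                                 call. = FALSE)
  chk(is.finite(p$Re) && p$Re > 0, "Re must be > 0")
  chk(is.finite(p$beta) && p$beta > 0, "beta must be > 0")
  chk(p$r > 0 && p$r < 1, "r must lie in (0, 1)")
  chk(p$lam >= 0, "lam must be >= 0")
  chk(p$Fr2 > 0, "Fr2 must be > 0")
  chk(p$N_i >= 4, "N_i must be >= 4")
  chk(p$N_k >= 4, "N_k must be >= 4")
  chk(p$N_kg >= 2 && p$N_kg < p$N_k, "N_kg must satisfy 2 <= N_kg < N_k")
  chk(p$dx > 0, "dx must be > 0")
  chk(p$dt > 0, "dt must be > 0")
  chk(p$L > 0 && p$L < p$L_r, "need 0 < L < L_r")
  chk(abs(p$N_i * p$dx - p$L_r) < 1e-9, "N_i * dx must equal L_r")
  chk(p$T_end > 0, "T_end must be > 0")
  chk(p$x_a >= 0 && p$x_b > p$x_a && p$x_b <= p$L,
      "need 0 <= x_a < x_b <= L")
  chk(p$t_avg_lo >= 0 && p$t_avg_hi > p$t_avg_lo,
      "need 0 <= t_avg_lo < t_avg_hi")
  chk(p$noise_amplitude >= 0, "noise_amplitude must be >= 0")
  chk(p$sponge_rate >= 0, "sponge_rate must be >= 0")
  chk(p$output_cadence > 0, "output_cadence must be > 0")
  chk(p$blade_nseg >= 4, "blade_nseg must be >= 4")
  chk(p$blade_tol > 0, "blade_tol must be > 0")
  chk(p$blade_relax > 0 && p$blade_relax <= 1, "blade_relax must be in (0,1]")
  chk(p$theta_fs >= 0.5 && p$theta_fs <= 1, "theta_fs must be in [0.5, 1]")
  chk(p$upwind_blend >= 0 && p$upwind_blend <= 1,
      "upwind_blend must be in [0,1]")
  invisible(p)
}

#' @exportS3Method base::print
print.monami_params <- function(x, ...) {
  cat("monami simulation parameters\n")
  cat(sprintf("  Re = %g, beta = %g, r = %g, lambda = %g, Fr^2 = %g\n",
              x$Re, x$beta, x$r, x$lam, x$Fr2))
  cat(sprintf("  grid %d x %d (%d canopy layers), dx = %g, dt = %g\n",
              x$N_i, x$N_k, x$N_kg, x$dx, x$dt))
  cat(sprintf("  channel L = %g (+ sponge to %g), T_end = %g\n",
              x$L, x$L_r, x$T_end))
  cat(sprintf("  noise %g (seed %d), exchange window [%g, %g], averaging [%g, %g]\n",
              x$noise_amplitude, x$rng_seed, x$x_a, x$x_b,
              x$t_avg_lo, x$t_avg_hi))
  invisible(x)
}

#' Cell-center x coordinates
#' @param p a `monami_params` object
#' @return numeric vector of length `N_i`
#' @export
x_centers <- function(p) (seq_len(p$N_i) - 0.5) * p$dx

#' Load a run configuration file
#'
#' Reads a flat YAML (key: value) file of parameter overrides and returns a
#' validated [sim_params()] object. Unknown keys are an error; missing keys
#' take the baseline defaults. An empty file yields the full baseline.
#'
#' @param path path to a YAML config file
#' @return a `monami_params` object
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("config must be a mapping of key: value pairs",
                          call. = FALSE)
  known <- names(formals(sim_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(sim_params, cfg)
}
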