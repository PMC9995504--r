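# Buoyant, inextensible, zero-flexural-rigidity blade statics.
#
# A blade is parameterised by arc length s in [0, ell] with clockwise angle
# theta(s) from the vertical. The three forces on a blade element are tension
# (along the blade), quadratic normal drag, and buoyancy; shear resistance,
# tangential drag, blade inertia, added mass and virtual buoyancy are
# neglected. The force balance dT/ds + f + beta * zhat = 0 with T(ell) = 0 is
# integrated tip-to-root, theta = atan(T^x / T^z) (tension is tangential, so
# a blade that does not overturn has T^z > 0), and the shape follows from
# dx_g/ds = sin(theta), dz_g/ds = cos(theta) integrated root-to-tip.
#
# All blades of a canopy are solved simultaneously: the internal routines act
# on (n_blade x n_node) matrices.

#' Arc-length node grid of a blade
#' @param ell blade length
#' @param nseg number of uniform segments
#' @return numeric vector of `nseg + 1` node positions in `[0, ell]`
#' @export
blade_s_nodes <- function(ell, nseg) seq(0, ell, length.out = nseg + 1L)

#' Quadratic normal drag on a blade element
#'
#' Drag per unit blade length for a blade element at angle `theta`, given the
#' signed normal velocity component `u_normal = u . nhat` with upstream normal
#' `nhat = (-cos(theta), sin(theta))`. The drag vector is
#' `f = (1/2) u_normal |u_normal| nhat`: magnitude `u_normal^2 / 2`, directed
#' along the blade-normal component of the local velocity, so that flow in +x
#' past a near-vertical blade pushes it downstream (`f_x > 0`). The expression
#' is invariant under flipping the normal's orientation.
#'
#' @param u_normal signed normal velocity component(s)
#' @param theta blade angle(s), radians clockwise from vertical
#' @return matrix with columns `fx`, `fz`
#' @export
blade_drag_per_length <- function(u_normal, theta) {
  q <- 0.5 * u_normal * abs(u_normal)
  cbind(fx = -q * cos(theta), fz = q * sin(theta))
}

#' Integrate blade tension from tip to root
#'
#' Trapezoidal integration of `T(s) = int_s^ell (f + beta zhat) ds'`, so that
#' the tip tension is exactly zero.
#'
#' @param f matrix of drag per unit length at the nodes (columns `fx`, `fz`)
#' @param beta buoyancy parameter
#' @param s_grid node positions (uniform)
#' @return matrix with columns `Tx`, `Tz`
#' @export
integrate_tension <- function(f, beta, s_grid) {
  nn <- length(s_grid)
  stopifnot(nrow(f) == nn)
  ds <- s_grid[2L] - s_grid[1L]
  gx <- f[, 1L]
  gz <- f[, 2L] + beta
  Tx <- rev(c(0, cumsum(0.5 * ds * (rev(gx)[-nn] + rev(gx)[-1L]))))
  Tz <- rev(c(0, cumsum(0.5 * ds * (rev(gz)[-nn] + rev(gz)[-1L]))))
  if (any(Tz[-nn] < 0))
    stop("blade overturning: negative vertical tension", call. = FALSE)
  cbind(Tx = Tx, Tz = Tz)
}

#' Blade angle from the tension profile
#'
#' `theta = atan(T^x / T^z)`, valid while the blade does not overturn
#' (`T^z > 0`). The tip, where the tension vanishes, takes its angle from the
#' direction of the local force integrand if `tip_direction` is supplied.
#'
#' @param tension matrix with columns `Tx`, `Tz`
#' @param tip_direction optional length-2 vector `(gx, gz)` of drag-plus-
#'   buoyancy at the tip, fixing the tip angle by the limit of `T` there
#' @return vector of angles in `(-pi/2, pi/2)`
#' @export
tension_to_angle <- function(tension, tip_direction = NULL) {
  Tx <- tension[, 1L]
  Tz <- tension[, 2L]
  nn <- length(Tx)
  if (any(Tz[-nn] <= 0))
    stop("blade overturning: non-positive vertical tension", call. = FALSE)
  th <- atan2(Tx, Tz)
  if (Tz[nn] <= 0) {
    if (!is.null(tip_direction)) {
      th[nn] <- atan2(tip_direction[1L], tip_direction[2L])
    } else if (Tz[nn] < 0) {
      stop("blade overturning: non-positive vertical tension", call. = FALSE)
    }
  }
  th
}

#' Blade shape from the angle profile
#'
#' Integrates `dx_g/ds = sin(theta)`, `dz_g/ds = cos(theta)` from the root
#' using the segment-mean angle, so every discrete segment has exactly length
#' `ds` and the blade is discretely inextensible.
#'
#' @param theta angles at the nodes
#' @param s_grid node positions (uniform)
#' @return matrix with columns `x_g`, `z_g`
#' @export
integrate_shape <- function(theta, s_grid) {
  ds <- s_grid[2L] - s_grid[1L]
  mid <- 0.5 * (theta[-length(theta)] + theta[-1L])
  cbind(x_g = c(0, cumsum(ds * sin(mid))),
        z_g = c(0, cumsum(ds * cos(mid))))
}

# --- vectorised multi-blade core -------------------------------------------

# Cumulative sum along rows (columns 1..j), with a leading zero column.
row_cum <- function(d) {
  nb <- nrow(d); nseg <- ncol(d)
  out <- matrix(0, nb, nseg + 1L)
  for (j in seq_len(nseg)) out[, j + 1L] <- out[, j] + d[, j]
  out
}

# Shape matrices from an angle matrix (n_blade x n_node).
blades_shape <- function(theta, ds) {
  nn <- ncol(theta)
  mid <- 0.5 * (theta[, -nn, drop = FALSE] + theta[, -1L, drop = FALSE])
  list(x_g = row_cum(ds * sin(mid)), z_g = row_cum(ds * cos(mid)))
}

# One fixed-point pass: angles -> shape -> sampled velocity -> drag ->
# tension -> candidate angles. `sampler(X, Z)` must return list(u, w) of the
# same shape. The candidate angle uses atan2 and is clamped short of pi/2 so
# the iteration can traverse transiently overturned intermediates; the
# overturning assumption (T^z > 0) is enforced on the converged state.
blades_candidate <- function(theta, root_x, beta, ds, sampler) {
  nb <- nrow(theta); nn <- ncol(theta)
  sh <- blades_shape(theta, ds)
  vel <- sampler(sh$x_g + root_x, sh$z_g)
  un <- -vel$u * cos(theta) + vel$w * sin(theta)
  q <- 0.5 * un * abs(un)
  gx <- -q * cos(theta)
  gz <- q * sin(theta) + beta
  # reverse cumulative trapezoid: T_j = sum_{m>=j} ds/2 (g_m + g_{m+1})
  Tx <- matrix(0, nb, nn); Tz <- matrix(0, nb, nn)
  for (j in (nn - 1L):1L) {
    Tx[, j] <- Tx[, j + 1L] + 0.5 * ds * (gx[, j] + gx[, j + 1L])
    Tz[, j] <- Tz[, j + 1L] + 0.5 * ds * (gz[, j] + gz[, j + 1L])
  }
  cand <- atan2(Tx, Tz)
  cand[, nn] <- atan2(gx[, nn], gz[, nn])  # tip: limit direction of T
  cand <- pmin(pmax(cand, -1.55), 1.55)
  list(theta = cand, Tx = Tx, Tz = Tz,
       x_g = sh$x_g, z_g = sh$z_g, u = vel$u, w = vel$w)
}

# Under-relaxed fixed point for all blades at once.
# Returns list(theta, x_g, z_g, Tx, Tz, iter, resid).
equilibrate_blades_core <- function(sampler, beta, ell, root_x, nseg,
                                    relax = 0.5, tol = 1e-6,
                                    max_iter = 200L, theta0 = NULL) {
  nb <- length(root_x)
  nn <- nseg + 1L
  ds <- ell / nseg
  theta <- if (is.null(theta0)) matrix(0, nb, nn) else theta0
  resid <- Inf
  relax_cur <- relax
  prev_resid <- Inf
  for (it in seq_len(max_iter)) {
    cc <- blades_candidate(theta, root_x, beta, ds, sampler)
    resid <- max(abs(cc$theta - theta))   # distance to the fixed point map
    if (resid < tol) {
      if (any(cc$Tz[, -nn] < 0)) {
        bad <- which(apply(cc$Tz[, -nn, drop = FALSE] < 0, 1L, any))
        stop("blade overturning in column(s) ",
             paste(utils::head(bad, 5L), collapse = ", "),
             ": non-positive vertical tension", call. = FALSE)
      }
      if (any(abs(theta) >= pi / 2))
        stop("blade overturning: |theta| >= pi/2", call. = FALSE)
      sh <- blades_shape(theta, ds)
      return(list(theta = theta, x_g = sh$x_g, z_g = sh$z_g,
                  Tx = cc$Tx, Tz = cc$Tz, iter = it, resid = resid))
    }
    # the plain under-relaxed map can cycle where the drag's vertical
    # component makes the tension nearly vanish: damp on residual growth,
    # recover slowly while the residual shrinks
    if (resid > prev_resid) {
      relax_cur <- max(0.5 * relax_cur, 0.02)
    } else {
      relax_cur <- min(relax, 1.05 * relax_cur)
    }
    prev_resid <- resid
    theta <- (1 - relax_cur) * theta + relax_cur * cc$theta
  }
  stop(sprintf(
    "blade equilibration did not converge in %d iterations (residual %.3e)",
    max_iter, resid), call. = FALSE)
}

#' Equilibrium shape of a single blade in a given velocity field
#'
#' Fixed point of the cycle sample-velocity -> normal drag -> tension ->
#' angle -> shape, with under-relaxation `theta <- (1 - relax) theta +
#' relax theta_candidate`, iterated until the largest angle update falls
#' below `tol`.
#'
#' @param velocity_sampler function `(x, z)` (vectorised, physical
#'   coordinates) returning `list(u, w)`
#' @param beta buoyancy parameter
#' @param ell blade length (defaults to the canopy height ratio `r`)
#' @param root_x x position of the blade root
#' @param nseg,relax,tol,max_iter iteration controls
#' @param theta0 optional starting angle profile (warm start)
#' @return an object of class `monami_blade`: fields `root_x`, `s_grid`,
#'   `theta`, `coords` (columns `x_g`, `z_g`), `tension` (columns `Tx`,
#'   `Tz`), `tip_height`, `iterations`, `residual`
#' @export
equilibrate_blade <- function(velocity_sampler, beta, ell = 0.5, root_x = 0,
                              nseg = 25L, relax = 0.5, tol = 1e-6,
                              max_iter = 200L, theta0 = NULL) {
  sampler <- function(X, Z) {
    v <- velocity_sampler(as.numeric(X), as.numeric(Z))
    list(u = matrix(v$u, nrow(X), ncol(X)),
         w = matrix(v$w, nrow(X), ncol(X)))
  }
  th0 <- if (is.null(theta0)) NULL else matrix(theta0, nrow = 1L)
  res <- equilibrate_blades_core(sampler, beta, ell, root_x, nseg,
                                 relax, tol, max_iter, th0)
  structure(list(root_x = root_x,
                 s_grid = blade_s_nodes(ell, nseg),
                 theta = as.numeric(res$theta),
                 coords = cbind(x_g = as.numeric(res$x_g),
                                z_g = as.numeric(res$z_g)),
                 tension = cbind(Tx = as.numeric(res$Tx),
                                 Tz = as.numeric(res$Tz)),
                 tip_height = res$z_g[1L, ncol(res$z_g)],
                 iterations = res$iter,
                 residual = res$resid),
            class = "monami_blade")
}

#' @exportS3Method base::print
print.monami_blade <- function(x, ...) {
  cat(sprintf(
    "blade at x = %.3f: tip height %.4f, root angle %.4f rad, %d iterations\n",
    x$root_x, x$tip_height, x$theta[1L], x$iterations))
  invisible(x)
}

#' Equilibrium angle of a straight blade in uniform horizontal flow
#'
#' In a uniform flow `(u0, 0)` the equilibrated blade is straight with a
#' constant angle `theta*` satisfying
#' `tan(theta) = (u0^2/2) cos^3(theta) / (beta - (u0^2/2) cos^2(theta) sin(theta))`,
#' the ratio of the horizontal to vertical tension components under normal
#' drag plus buoyancy. Solved by bisection; used as an independent oracle for
#' the fixed-point solver.
#'
#' @param u0 uniform horizontal speed
#' @param beta buoyancy parameter
#' @param tol bisection tolerance
#' @return the angle `theta*` in `[0, pi/2)`
#' @export
uniform_flow_angle <- function(u0, beta, tol = 1e-12) {
  g <- function(th) {
    tz <- beta - 0.5 * u0^2 * cos(th)^2 * sin(th)
    sin(th) * tz - 0.5 * u0^2 * cos(th)^4   # tan(th) tz - fx, times cos(th)
  }
  lo <- 0; hi <- pi / 2 - 1e-9
  if (g(hi) < 0) stop("no non-overturning equilibrium for u0 = ", u0,
                      ", beta = ", beta, call. = FALSE)
  while (hi - lo > tol) {
    mid <- 0.5 * (lo + hi)
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  0.5 * (lo + hi)
}
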