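# Two-way fluid-blade coupling: equilibrate one blade representative per
# column against the current velocity field, rebuild the canopy-top height
# from the blade tips, and assemble the homogenized volumetric drag on the
# fluid. Within the grass phase F = -lambda sec(theta) f (reaction to the
# blade drag, amplified by the effective blade-density increase when
# neighbouring plants tilt); F = 0 in the overflow.

#' Equilibrate all blade representatives against a velocity field
#'
#' One blade is rooted at each cell-center abscissa. Each blade is driven to
#' its drag-buoyancy-tension equilibrium by the under-relaxed fixed point of
#' [equilibrate_blade()], all columns advancing together. The canopy-top
#' profile is the (natural cubic) spline through the blade tips evaluated at
#' the roots -- which the spline interpolates exactly, so `h_g(x_i)` equals
#' the tip height of blade `i`, clipped to `[0.05 r, 0.999 h]`.
#'
#' @param uc,wc cell-centered velocity components (`N_i x N_k`)
#' @param mapping current grid mapping
#' @param params a [sim_params()] object
#' @param theta0 optional `N_i x (nseg+1)` warm-start angle matrix
#' @param tol override of the blade convergence tolerance
#' @return list with `blades` (class `monami_blades`: angle/shape/force
#'   matrices over columns x arc-length nodes) and `h_g` (canopy height per
#'   column)
#' @export
equilibrate_canopy <- function(uc, wc, mapping, params, theta0 = NULL,
                               tol = params$blade_tol) {
  sampler <- make_velocity_sampler(uc, wc, mapping)
  rx <- x_centers(params)
  res <- equilibrate_blades_core(sampler, params$beta, params$r, rx,
                                 params$blade_nseg, params$blade_relax,
                                 tol, params$blade_max_iter, theta0)
  blades <- blades_finalize(res, rx, params, sampler)
  tips <- blades$z_g[, ncol(blades$z_g)]
  h_g <- pmin(pmax(tips, 0.05 * params$r), 0.999 * mapping$h)
  list(blades = blades, h_g = h_g)
}

# Recompute drag per unit length at the converged shape (stored with the
# blades so that deposition and the blade solve see the same forces).
blades_finalize <- function(res, root_x, params, sampler) {
  theta <- res$theta
  vel <- sampler(res$x_g + root_x, res$z_g)
  un <- -vel$u * cos(theta) + vel$w * sin(theta)
  q <- 0.5 * un * abs(un)
  structure(list(theta = theta, x_g = res$x_g, z_g = res$z_g,
                 fx = -q * cos(theta), fz = q * sin(theta),
                 Tx = res$Tx, Tz = res$Tz,
                 root_x = root_x, ell = params$r,
                 nseg = params$blade_nseg,
                 iterations = res$iter, residual = res$resid),
            class = "monami_blades")
}

#' @exportS3Method base::print
print.monami_blades <- function(x, ...) {
  tips <- x$z_g[, ncol(x$z_g)]
  cat(sprintf(
    "%d blade representatives: tip heights in [%.4f, %.4f], %d equilibration iterations\n",
    length(x$root_x), min(tips), max(tips), x$iterations))
  invisible(x)
}

#' Distribute blade drag onto the grid as a volumetric force
#'
#' Each blade segment carries a force `-lambda sec(theta) f` per unit length
#' times its length (trapezoid over the segment's end nodes). The force is
#' spread in x over neighbouring columns with a discrete Gaussian kernel
#' centered on the segment (standard deviation `0.3 dx`, truncated at
#' `+/- 3 sd`, renormalized to unit sum) and in z over the canopy cell rows
#' overlapped by the segment's vertical extent, proportionally to overlap.
#' Edge columns are padded with replicas of the boundary blades so a
#' horizontally uniform canopy yields an exactly uniform force. The result
#' is force per unit volume, zero above the canopy interface.
#'
#' @param blades a `monami_blades` set from [equilibrate_canopy()]
#' @param mapping current grid mapping
#' @param params a [sim_params()] object
#' @return list of class `monami_dragfield` with `Fx`, `Fz` (`N_i x N_k`,
#'   force per unit volume on the fluid)
#' @export
distribute_drag <- function(blades, mapping, params) {
  N_i <- mapping$N_i; N_k <- mapping$N_k; N_kg <- mapping$N_kg
  dx <- mapping$dx
  lam <- params$lam
  nn <- blades$nseg + 1L
  ds <- blades$ell / blades$nseg
  # pad with ghost blades beyond both ends (deflection can reach
  # ceil(ell/dx) columns downstream of the root)
  gl <- as.integer(ceiling(blades$ell / dx)) + 1L
  gr <- 1L
  idx <- c(rep(1L, gl), seq_len(nrow(blades$theta)), rep(N_i, gr))
  roots <- c(blades$root_x[1L] - (gl:1) * dx, blades$root_x,
             blades$root_x[N_i] + (1:gr) * dx)
  th <- blades$theta[idx, , drop = FALSE]
  xg <- blades$x_g[idx, , drop = FALSE]
  zg <- blades$z_g[idx, , drop = FALSE]
  sec_t <- 1 / cos(pmin(abs(th), params$sec_clamp))
  gx <- -lam * sec_t * blades$fx[idx, , drop = FALSE]
  gz <- -lam * sec_t * blades$fz[idx, , drop = FALSE]
  # per-segment force (trapezoid over end nodes) and position
  segFx <- 0.5 * ds * (gx[, -nn, drop = FALSE] + gx[, -1L, drop = FALSE])
  segFz <- 0.5 * ds * (gz[, -nn, drop = FALSE] + gz[, -1L, drop = FALSE])
  segx <- roots + 0.5 * (xg[, -nn, drop = FALSE] + xg[, -1L, drop = FALSE])
  segzlo <- zg[, -nn, drop = FALSE]
  segzhi <- zg[, -1L, drop = FALSE]
  ns <- length(segx)
  segFx <- as.numeric(segFx); segFz <- as.numeric(segFz)
  segx <- as.numeric(segx)
  segzlo <- as.numeric(segzlo); segzhi <- as.numeric(segzhi)
  # x kernel: candidate columns nearest the segment and its two neighbours
  sdk <- 0.3 * dx
  m0 <- round(segx / dx + 0.5)
  wsum <- 0
  offs <- -1:1
  wx <- matrix(0, ns, 3L)
  mm <- matrix(0L, ns, 3L)
  for (j in 1:3) {
    m <- m0 + offs[j]
    d <- (m - 0.5) * dx - segx
    w <- ifelse(abs(d) <= 3 * sdk, exp(-0.5 * (d / sdk)^2), 0)
    mm[, j] <- m
    wx[, j] <- w
  }
  wx <- wx / rowSums(wx)
  # z deposition rows per (segment, column) pair
  Fx <- matrix(0, N_i, N_k)
  Fz <- matrix(0, N_i, N_k)
  hgv <- mapping$hg
  acc_i <- integer(0); acc_x <- numeric(0); acc_z <- numeric(0)
  for (j in 1:3) {
    m <- mm[, j]
    keep <- which(m >= 1L & m <= N_i & wx[, j] > 0)
    if (!length(keep)) next
    m <- m[keep]
    fxk <- segFx[keep] * wx[keep, j]
    fzk <- segFz[keep] * wx[keep, j]
    dzc <- hgv[m] / N_kg
    zl <- pmin(pmax(segzlo[keep], 0), hgv[m])
    zh <- pmin(pmax(segzhi[keep], 0), hgv[m])
    ext <- zh - zl
    kl <- pmin(pmax(ceiling(zl / dzc), 1L), N_kg)
    nrow_max <- max(2L, min(N_kg, max(ceiling(ext / dzc)) + 1L))
    degen <- ext <= 0
    for (q in seq_len(nrow_max) - 1L) {
      kr <- kl + q
      inr <- kr <= N_kg    # the clamped extent is fully covered by rows
      kr[!inr] <- N_kg     # <= N_kg; rows beyond contribute nothing
      ov <- inr * pmax(0, pmin(zh, kr * dzc) - pmax(zl, (kr - 1) * dzc))
      frac <- ifelse(degen, ifelse(q == 0L, 1, 0), ov / pmax(ext, 1e-300))
      use <- frac > 0
      if (!any(use)) next
      lin <- m[use] + (kr[use] - 1L) * N_i
      acc_i <- c(acc_i, lin)
      acc_x <- c(acc_x, fxk[use] * frac[use])
      acc_z <- c(acc_z, fzk[use] * frac[use])
    }
  }
  if (length(acc_i)) {
    o <- order(acc_i)
    io <- acc_i[o]
    ends <- c(which(io[-1L] != io[-length(io)]), length(io))
    lin <- io[ends]
    csx <- cumsum(acc_x[o])[ends]
    csz <- cumsum(acc_z[o])[ends]
    sx <- csx - c(0, csx[-length(csx)])
    sz <- csz - c(0, csz[-length(csz)])
    vol <- dx * mapping$dz[lin]
    Fx[lin] <- sx / vol
    Fz[lin] <- sz / vol
  }
  structure(list(Fx = Fx, Fz = Fz), class = "monami_dragfield")
}

#' One coupling pass: blades, canopy height, drag field
#'
#' Composition of [equilibrate_canopy()] and [distribute_drag()], executed
#' once per time step before the momentum predictor (the drag lags the
#' velocity update by one step; the blades are always in equilibrium with
#' the flow they last saw).
#'
#' @inheritParams equilibrate_canopy
#' @return list with `blades`, `h_g`, `drag`
#' @export
couple_step <- function(uc, wc, mapping, params, theta0 = NULL,
                        tol = params$blade_tol) {
  can <- equilibrate_canopy(uc, wc, mapping, params, theta0, tol)
  drag <- distribute_drag(can$blades, mapping, params)
  list(blades = can$blades, h_g = can$h_g, drag = drag)
}
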