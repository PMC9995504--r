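# Scalar and field diagnostics: rms metrics, Hovmoeller extraction,
# vortex-street kinematics, onset detection, long-term averages, and the
# (Re, beta) parametric sweep.

# w at cell centers of a state.
w_centers <- function(state) {
  N_k <- state$mapping$N_k
  0.5 * (state$w[, -(N_k + 1L), drop = FALSE] + state$w[, -1L, drop = FALSE])
}

# Linear interpolation of a cell-centered field to a fixed physical level,
# per column. Returns a length-N_i vector.
field_at_level <- function(field, mapping, level) {
  N_i <- mapping$N_i; N_k <- mapping$N_k
  fi <- frac_center_index(matrix(level, N_i, 1L), matrix(mapping$hg, N_i),
                          matrix(mapping$h, N_i), mapping$N_kg, N_k)
  fi <- pmin(pmax(fi, 1), N_k)
  k0 <- pmin(floor(fi), N_k - 1L)
  tz <- fi - k0
  as.numeric((1 - tz) * field[cbind(seq_len(N_i), as.integer(k0))] +
               tz * field[cbind(seq_len(N_i), as.integer(k0) + 1L)])
}

# Per-sample diagnostics of a state against its steady profile; `cols` is
# the set of columns inside the analysis domain (x <= L).
state_diagnostics <- function(state, cols = NULL) {
  params <- state$params
  if (is.null(cols)) cols <- which(x_centers(params) <= params$L)
  wc <- w_centers(state)
  wa <- wc[cols, , drop = FALSE]
  hbg <- state$steady$h_bar_g
  phi <- vertical_flux(state)
  list(t = state$t,
       w_rms = sqrt(mean(wa^2)),
       dhg_rms = sqrt(mean((state$hg[cols] - hbg)^2)),
       Phi = exchange(phi, state$mapping, params$x_a, params$x_b, hbg),
       hov = field_at_level(wc, state$mapping, hbg),
       w_xrms = sqrt(colMeans(wa^2)))
}

#' Recompute the diagnostic series from stored states
#'
#' Applies the in-run diagnostic formulas (`w_rms`: uniform-weight rms of
#' the vertical velocity over all analysis-domain cells; `dhg_rms`: rms of
#' the canopy-height perturbation about the steady height over columns;
#' tracer exchange `Phi`; the canopy-top Hovmoeller row `w(x, z = h_bar_g)`
#' and the per-level `w_xrms(z)`) to a list of saved states.
#'
#' @param states list of `monami_state` snapshots
#' @return a list with `series` (data frame `t`, `w_rms`, `dhg_rms`,
#'   `Phi`), `hovmoller` (time x column matrix) and `w_xrms`
#'   (time x level matrix)
#' @export
compute_rms_series <- function(states) {
  ds <- lapply(states, state_diagnostics)
  list(series = data.frame(t = vapply(ds, `[[`, 0, "t"),
                           w_rms = vapply(ds, `[[`, 0, "w_rms"),
                           dhg_rms = vapply(ds, `[[`, 0, "dhg_rms"),
                           Phi = vapply(ds, `[[`, 0, "Phi")),
       hovmoller = do.call(rbind, lapply(ds, `[[`, "hov")),
       w_xrms = do.call(rbind, lapply(ds, `[[`, "w_xrms")))
}

# Quadratic (three-point) interpolation of a discrete spectral peak.
# Returns the refined fractional index of the maximum.
peak_interp <- function(p, m) {
  if (m <= 1L || m >= length(p)) return(m)
  d2 <- p[m - 1L] - 2 * p[m] + p[m + 1L]
  if (d2 >= 0) return(m)
  m + 0.5 * (p[m - 1L] - p[m + 1L]) / d2
}

# Mean periodogram over the rows of a matrix (series along columns), with
# a Hann taper to keep the quadratic peak interpolation unbiased by leakage.
mean_power <- function(M) {
  M <- sweep(M, 2L, colMeans(M))
  n <- nrow(M)
  M <- M * (0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / n))
  P <- abs(stats::mvfft(M))^2
  rowMeans(P)[2:floor(n / 2)]   # drop the mean; one-sided
}

#' Estimate vortex-street kinematics from a Hovmoeller diagram
#'
#' Wavelength from the peak of the time-averaged spatial power spectrum,
#' period from the peak of the space-averaged temporal power spectrum (both
#' refined by quadratic interpolation), and propagation speed from the lag
#' maximizing the space-time cross-correlation between samples one output
#' interval apart, averaged over the window.
#'
#' @param hovmoller time x column matrix of `w(x, z = h_bar_g, t)`
#' @param dx column spacing
#' @param sample_dt time spacing of the rows
#' @param t_samples times of the rows (defaults to `0, dt, ...`)
#' @param x_samples x of the columns (defaults to cell centers)
#' @param t_window,x_window analysis window (defaults `[300, 500]` and
#'   `[20, 34]`)
#' @param min_peak_ratio spectral peak must exceed this multiple of the mean
#'   spectral level, else no street is reported
#' @return object of class `monami_street` with `speed`, `period`,
#'   `wavelength`, `detected`
#' @export
estimate_street <- function(hovmoller, dx, sample_dt,
                            t_samples = NULL, x_samples = NULL,
                            t_window = c(300, 500), x_window = c(20, 34),
                            min_peak_ratio = 8) {
  nt <- nrow(hovmoller); nx <- ncol(hovmoller)
  if (is.null(t_samples)) t_samples <- (seq_len(nt) - 1L) * sample_dt
  if (is.null(x_samples)) x_samples <- (seq_len(nx) - 0.5) * dx
  ri <- which(t_samples >= t_window[1L] & t_samples <= t_window[2L])
  ci <- which(x_samples >= x_window[1L] & x_samples <= x_window[2L])
  if (length(ri) < 8L) ri <- seq_len(nt)
  if (length(ci) < 8L) ci <- seq_len(nx)
  if (length(ri) < 8L || length(ci) < 8L) {
    return(structure(list(speed = NA_real_, period = NA_real_,
                          wavelength = NA_real_, detected = FALSE,
                          consistency = NA_real_),
                     class = "monami_street"))
  }
  H <- hovmoller[ri, ci, drop = FALSE]
  H <- H - mean(H)
  nxw <- ncol(H); ntw <- nrow(H)
  if (!any(H != 0)) {
    return(structure(list(speed = NA_real_, period = NA_real_,
                          wavelength = NA_real_, detected = FALSE,
                          consistency = NA_real_),
                     class = "monami_street"))
  }
  # spatial spectrum: series along x for each time
  Ps <- mean_power(t(H))
  ms <- which.max(Ps)
  det_s <- Ps[ms] > min_peak_ratio * mean(Ps)
  fs <- peak_interp(Ps, ms) / (nxw * dx)        # cycles per unit length
  wavelength <- 1 / fs
  # temporal spectrum: series along t for each x
  Pt <- mean_power(H)
  mt <- which.max(Pt)
  det_t <- Pt[mt] > min_peak_ratio * mean(Pt)
  ft <- peak_interp(Pt, mt) / (ntw * sample_dt)
  period <- 1 / ft
  # phase speed: lag of maximum cross-correlation between successive rows,
  # searched within half the measured wavelength to avoid the periodic
  # ambiguity of the correlation function
  max_lag <- min(nxw - 2L,
                 max(2L, floor(0.5 * wavelength / dx)))
  lags <- -max_lag:max_lag
  cc <- numeric(length(lags))
  for (li in seq_along(lags)) {
    l <- lags[li]
    if (l >= 0) {
      a <- H[-ntw, seq_len(nxw - l), drop = FALSE]
      b <- H[-1L, seq_len(nxw - l) + l, drop = FALSE]
    } else {
      a <- H[-ntw, seq_len(nxw + l) - l, drop = FALSE]
      b <- H[-1L, seq_len(nxw + l), drop = FALSE]
    }
    cc[li] <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  ml <- which.max(cc)
  speed <- peak_interp(cc, ml) - (max_lag + 1L)
  speed <- speed * dx / sample_dt
  structure(list(speed = speed, period = period, wavelength = wavelength,
                 detected = det_s && det_t,
                 consistency = abs(speed - wavelength / period) /
                   max(abs(speed), 1e-12)),
            class = "monami_street")
}

#' @exportS3Method base::print
print.monami_street <- function(x, ...) {
  if (!x$detected) {
    cat("no vortex street detected\n")
  } else {
    cat(sprintf(
      "vortex street: speed %.3f, period %.3f, wavelength %.3f (speed vs wavelength/period: %.1f%%)\n",
      x$speed, x$period, x$wavelength, 100 * x$consistency))
  }
  invisible(x)
}

#' Instability onset time from a w_rms series
#'
#' First time at which `w_rms` exceeds `threshold` for `sustain`
#' consecutive samples.
#'
#' @param t sample times
#' @param w_rms the series
#' @param threshold onset threshold
#' @param sustain number of consecutive samples required
#' @return onset time, or `NA` if never sustained
#' @export
detect_onset <- function(t, w_rms, threshold = 1e-3, sustain = 5L) {
  above <- w_rms > threshold
  n <- length(above)
  if (n < sustain) return(NA_real_)
  run <- stats::filter(as.numeric(above), rep(1, sustain), sides = 1L)
  hit <- which(run == sustain)
  if (!length(hit)) return(NA_real_)
  t[hit[1L] - sustain + 1L]
}

#' Long-term average of a series over a window
#' @param t sample times
#' @param y series values
#' @param t_lo,t_hi averaging window
#' @return list with `mean` and `rms_dev` (rms deviation from the mean)
#' @export
long_term_average <- function(t, y, t_lo, t_hi) {
  sel <- t >= t_lo & t <= t_hi
  if (!any(sel)) return(list(mean = NA_real_, rms_dev = NA_real_))
  m <- mean(y[sel])
  list(mean = m, rms_dev = sqrt(mean((y[sel] - m)^2)))
}

#' Height of the vortex cores from the final w_xrms profile
#' @param run a `monami_run`
#' @return z of the maximum of `w_xrms(z)` at the last sample
#' @export
core_height <- function(run) {
  prof <- run$w_xrms[nrow(run$w_xrms), ]
  zc <- column_z_centers(run$steady$h_bar_g, 1, run$params)
  zc[which.max(prof)]
}

#' Parametric (Re, beta) stability sweep
#'
#' One full simulation per parameter combination; long-term (averaging
#' window) statistics of `w_rms`, `dhg_rms` and `Phi` are recorded, with
#' the stability mask defined by long-term `w_rms` above `threshold`.
#' Reduced grids and run lengths are set through `base_params`.
#'
#' @param base_params template [sim_params()]
#' @param Re_values,beta_values sweep coordinates
#' @param threshold stability threshold on long-term `w_rms`
#' @param verbose print one line per run
#' @return object of class `monami_phase`: matrices `w_rms_longterm`,
#'   `dhg_rms_longterm`, `Phi_star` (`length(Re_values)` x
#'   `length(beta_values)`), logical `stable_mask`, and `errors`
#' @export
run_sweep <- function(base_params, Re_values, beta_values,
                      threshold = 1e-4, verbose = FALSE) {
  nr <- length(Re_values); nb <- length(beta_values)
  wlt <- dlt <- plt <- matrix(NA_real_, nr, nb,
                              dimnames = list(Re_values, beta_values))
  errs <- list()
  for (i in seq_len(nr)) for (j in seq_len(nb)) {
    pij <- base_params
    pij$Re <- Re_values[i]
    pij$beta <- beta_values[j]
    res <- tryCatch({
      run <- run_simulation(pij)
      sr <- run$series
      c(long_term_average(sr$t, sr$w_rms, pij$t_avg_lo, pij$t_avg_hi)$mean,
        long_term_average(sr$t, sr$dhg_rms, pij$t_avg_lo, pij$t_avg_hi)$mean,
        long_term_average(sr$t, sr$Phi, pij$t_avg_lo, pij$t_avg_hi)$mean)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs[[sprintf("Re%g_beta%g", Re_values[i], beta_values[j])]] <-
        conditionMessage(res)
    } else {
      wlt[i, j] <- res[1L]; dlt[i, j] <- res[2L]; plt[i, j] <- res[3L]
    }
    if (verbose)
      message(sprintf("sweep Re = %g, beta = %g: w_rms = %.4g",
                      Re_values[i], beta_values[j], wlt[i, j]))
  }
  structure(list(Re_grid = Re_values, beta_grid = beta_values,
                 w_rms_longterm = wlt, dhg_rms_longterm = dlt,
                 Phi_star = plt, stable_mask = !(wlt > threshold),
                 threshold = threshold, errors = errs),
            class = "monami_phase")
}

#' @exportS3Method base::print
print.monami_phase <- function(x, ...) {
  cat(sprintf("(Re, beta) sweep: %d x %d runs, %d failed\n",
              length(x$Re_grid), length(x$beta_grid), length(x$errors)))
  cat("long-term w_rms:\n")
  print(signif(x$w_rms_longterm, 3))
  invisible(x)
}
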