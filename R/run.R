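# Full simulation driver: steady base state, initialization, time loop,
# streaming diagnostics, snapshots.

#' Run a coupled canopy-channel simulation
#'
#' Solves the 1D steady base state (unless supplied), initializes the
#' channel with it plus seeded noise on the vertical velocity, advances to
#' `T_end`, and records the diagnostic series (`w_rms`, `dhg_rms`, tracer
#' exchange `Phi`), the canopy-top Hovmoeller diagram and the per-level
#' `w_xrms` at every `output_cadence`.
#'
#' @param params a [sim_params()] object
#' @param steady optional precomputed [solve_steady()] profile
#' @param verbose print a progress line every 100 steps
#' @return object of class `monami_run`: `params`, `steady`, `series`
#'   (data frame), `hovmoller`, `w_xrms`, `t_samples`, `snapshots` (list,
#'   one per `snapshot_cadence` if finite), `final_state`, `onset_time`,
#'   `log`
#' @export
run_simulation <- function(params, steady = NULL, verbose = FALSE) {
  if (is.null(steady)) steady <- solve_steady(params)
  state <- initialize_state(params, steady)
  nsteps <- round(params$T_end / params$dt)
  every <- max(1L, round(params$output_cadence / params$dt))
  snap_every <- if (is.finite(params$snapshot_cadence)) {
    max(1L, round(params$snapshot_cadence / params$dt))
  } else NA_integer_
  cols <- which(x_centers(params) <= params$L)
  max_div <- 0
  recs <- vector("list", nsteps %/% every + 1L)
  recs[[1L]] <- state_diagnostics(state, cols)
  snaps <- list()
  budgets <- if (isTRUE(params$collect_budget)) vector("list", nsteps)
  log <- character(0)
  ir <- 1L
  for (n in seq_len(nsteps)) {
    state <- tryCatch(step_flow(state, params), error = function(e) e)
    if (inherits(state, "error")) {
      msg <- conditionMessage(state)
      if (grepl("^CFL violation", msg) && params$upwind_blend < 0.1 &&
          n > 1L) {
        # documented fallback: blend 10% first-order upwind into the
        # momentum advection (with the guard moved to the true Courant
        # limit) and continue from the last stable state
        params$upwind_blend <- 0.1
        params$cfl_max <- max(params$cfl_max, 0.99)
        log <- c(log, sprintf(
          "step %d: %s; enabled 10%% upwind blend and continued", n, msg))
        state <- prev_state
        state$params <- params
        state <- step_flow(state, params)
      } else {
        stop(state)
      }
    }
    prev_state <- state
    max_div <- max(max_div, state$last_divergence)
    if (isTRUE(params$collect_budget)) budgets[[n]] <- state$budget
    if (n %% every == 0L) {
      ir <- ir + 1L
      recs[[ir]] <- state_diagnostics(state, cols)
    }
    if (!is.na(snap_every) && n %% snap_every == 0L)
      snaps[[length(snaps) + 1L]] <- state
    if (verbose && n %% 100L == 0L) {
      d <- recs[[ir]]
      message(sprintf(
        "t = %6.1f  w_rms = %.3e  dhg_rms = %.3e  Phi = %.3e  div = %.1e  blade_it = %d",
        state$t, d$w_rms, d$dhg_rms, d$Phi, state$last_divergence,
        state$blade_iters))
    }
  }
  recs <- recs[seq_len(ir)]
  series <- data.frame(t = vapply(recs, `[[`, 0, "t"),
                       w_rms = vapply(recs, `[[`, 0, "w_rms"),
                       dhg_rms = vapply(recs, `[[`, 0, "dhg_rms"),
                       Phi = vapply(recs, `[[`, 0, "Phi"))
  structure(list(params = params, steady = steady,
                 series = series,
                 hovmoller = do.call(rbind, lapply(recs, `[[`, "hov")),
                 w_xrms = do.call(rbind, lapply(recs, `[[`, "w_xrms")),
                 t_samples = series$t,
                 snapshots = snaps,
                 final_state = state,
                 onset_time = detect_onset(series$t, series$w_rms),
                 max_divergence = max_div,
                 budgets = budgets,
                 log = log),
            class = "monami_run")
}

#' @exportS3Method base::print
print.monami_run <- function(x, ...) {
  cat(sprintf("canopy-channel run to t = %g (Re = %g, beta = %g)\n",
              max(x$t_samples), x$params$Re, x$params$beta))
  lt <- long_term_average(x$series$t, x$series$w_rms,
                          x$params$t_avg_lo, x$params$t_avg_hi)
  cat(sprintf("  onset at t = %s, long-term w_rms = %.4g\n",
              format(x$onset_time), lt$mean))
  cat(sprintf("  final h_g range [%.4f, %.4f] about steady %.4f\n",
              min(x$final_state$hg), max(x$final_state$hg),
              x$steady$h_bar_g))
  invisible(x)
}

#' @export
plot.monami_run <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(x$series$t, x$series$w_rms, type = "l", log = "y",
       xlab = "t", ylab = "w_rms", main = "instability growth", ...)
  image(x$t_samples, (seq_len(ncol(x$hovmoller)) - 0.5) * x$params$dx,
        x$hovmoller, xlab = "t", ylab = "x",
        main = "w at the canopy top", ...)
  invisible(x)
}
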