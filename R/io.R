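# Persistence and command-line entry points.
#
# A run is written as three files in an output directory:
#   series.csv   -- diagnostic time series (t, w_rms, dhg_rms, Phi)
#   run.rds      -- the full gridded output (final state, snapshots,
#                   Hovmoeller array, steady profile, parameters)
#   meta.json    -- scalar metadata: parameters, steady-state summary,
#                   onset time, street kinematics, package version
# The gridded container is an RDS file whose structure is documented in
# ?run_simulation; series and scalars are plain text.

run_metadata <- function(run) {
  lt <- long_term_average(run$series$t, run$series$w_rms,
                          run$params$t_avg_lo, run$params$t_avg_hi)
  ltd <- long_term_average(run$series$t, run$series$dhg_rms,
                           run$params$t_avg_lo, run$params$t_avg_hi)
  ltp <- long_term_average(run$series$t, run$series$Phi,
                           run$params$t_avg_lo, run$params$t_avg_hi)
  list(params = unclass(run$params),
       package_version = as.character(utils::packageVersion("monami")),
       h_bar_g = run$steady$h_bar_g,
       forcing_G = run$steady$forcing_G,
       onset_time = run$onset_time,
       w_rms_longterm = lt$mean,
       dhg_rms_longterm = ltd$mean,
       Phi_star = ltp$mean,
       hg_final_min = min(run$final_state$hg),
       hg_final_max = max(run$final_state$hg),
       log = run$log)
}

#' Write a simulation run to an output directory
#'
#' @param run a `monami_run`
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$series, file.path(out_dir, "series.csv"),
                   row.names = FALSE)
  saveRDS(run, file.path(out_dir, "run.rds"))
  jsonlite::write_json(run_metadata(run), file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a steady profile to CSV with a JSON sidecar
#'
#' @param profile a `monami_steady`
#' @param csv_path path of the CSV (columns `z`, `u_bar`, `theta_bar`)
#' @param json_path path of the JSON sidecar (`h_bar_g`, `G`, `iterations`);
#'   defaults next to the CSV
#' @return `csv_path`, invisibly
#' @export
write_steady <- function(profile, csv_path,
                         json_path = sub("\\.csv$", ".json", csv_path)) {
  utils::write.csv(data.frame(z = profile$z_levels,
                              u_bar = profile$u_bar,
                              theta_bar = profile$theta_bar),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(list(h_bar_g = profile$h_bar_g,
                            G = profile$forcing_G,
                            iterations = profile$iterations),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}

parse_range <- function(txt) {
  v <- as.numeric(strsplit(txt, ":", fixed = TRUE)[[1L]])
  if (length(v) == 1L) return(v)
  if (length(v) != 3L) stop("range must be lo:hi:step", call. = FALSE)
  seq(v[1L], v[2L], by = v[3L])
}

#' Command-line entry point
#'
#' Subcommands: `steady` (1D base state to CSV/JSON), `run` (full
#' simulation), `sweep` (parametric stability diagram), `diag` (recompute
#' diagnostics from a saved run). See `exec/monami` for the launcher.
#'
#' @param argv character vector of arguments (excluding the program name)
#' @return exit status, 0 on success
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    cat("usage: monami <steady|run|sweep|diag> [options]\n")
    return(1L)
  }
  cmd <- argv[1L]
  rest <- argv[-1L]
  opts <- list(config = NULL, out_dir = "monami-out", T_end = NA,
               seed = NA, cadence = NA, re = NULL, beta = NULL, run = NULL)
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[i]
    val <- if (i < length(rest)) rest[i + 1L] else NA
    adv <- 2L
    switch(key,
           "--config" = opts$config <- val,
           "--out-dir" = opts$out_dir <- val,
           "--T-end" = opts$T_end <- as.numeric(val),
           "--seed" = opts$seed <- as.integer(val),
           "--cadence" = opts$cadence <- as.numeric(val),
           "--re" = opts$re <- val,
           "--beta" = opts$beta <- val,
           "--run" = opts$run <- val,
           stop("unknown option: ", key, call. = FALSE))
    i <- i + adv
  }
  params <- if (!is.null(opts$config)) load_config(opts$config) else
    sim_params()
  if (!is.na(opts$T_end)) params$T_end <- opts$T_end
  if (!is.na(opts$seed)) params$rng_seed <- as.integer(opts$seed)
  if (!is.na(opts$cadence)) params$output_cadence <- opts$cadence
  validate_params(params)
  dir.create(opts$out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- tryCatch({
    switch(cmd,
           steady = {
             prof <- solve_steady(params)
             write_steady(prof, file.path(opts$out_dir, "profile.csv"))
             print(prof)
             0L
           },
           run = {
             run <- run_simulation(params)
             write_run(run, opts$out_dir)
             print(run)
             0L
           },
           sweep = {
             if (is.null(opts$re) || is.null(opts$beta))
               stop("sweep needs --re lo:hi:step and --beta lo:hi:step",
                    call. = FALSE)
             ph <- run_sweep(params, parse_range(opts$re),
                             parse_range(opts$beta), verbose = TRUE)
             saveRDS(ph, file.path(opts$out_dir, "phase.rds"))
             utils::write.csv(
               data.frame(Re = rep(ph$Re_grid, times = length(ph$beta_grid)),
                          beta = rep(ph$beta_grid, each = length(ph$Re_grid)),
                          w_rms = as.numeric(ph$w_rms_longterm),
                          dhg_rms = as.numeric(ph$dhg_rms_longterm),
                          Phi_star = as.numeric(ph$Phi_star),
                          stable = as.numeric(ph$stable_mask)),
               file.path(opts$out_dir, "phase.csv"), row.names = FALSE)
             print(ph)
             0L
           },
           diag = {
             if (is.null(opts$run))
               stop("diag needs --run <run.rds>", call. = FALSE)
             run <- readRDS(opts$run)
             states <- c(run$snapshots, list(run$final_state))
             dg <- compute_rms_series(states)
             utils::write.csv(dg$series,
                              file.path(opts$out_dir, "diag_series.csv"),
                              row.names = FALSE)
             st <- estimate_street(run$hovmoller, run$params$dx,
                                   run$params$output_cadence,
                                   t_samples = run$t_samples)
             jsonlite::write_json(unclass(st),
                                  file.path(opts$out_dir, "street.json"),
                                  auto_unbox = TRUE, digits = NA)
             print(st)
             0L
           },
           { cat("unknown command:", cmd, "\n"); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  status
}
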