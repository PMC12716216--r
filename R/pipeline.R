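# End-to-end runs: configuration handling and the four pipeline commands
# (couple, efficiency, titrate, rank-sites).  The command-line script in
# inst/cli/ is a thin wrapper over these functions, so library calls and
# CLI runs are the same code path.

#' Resolve a run configuration
#'
#' Accepts either a named list or the path to a YAML file; `overrides`
#' (e.g. parsed CLI flags) replace config keys.
#'
#' @param config named list or YAML file path.
#' @param overrides named list of overriding values.
#' @return Named list.
#' @export
resolve_config <- function(config, overrides = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  config[names(overrides)] <- overrides
  config
}

# write the resolved config and package version next to the outputs
write_run_metadata <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- config
  meta$package_version <- as.character(utils::packageVersion("trespfret"))
  yaml::write_yaml(meta, file.path(out_dir, "run_config.yaml"))
  invisible(out_dir)
}

require_keys <- function(config, keys, cmd) {
  missing <- setdiff(keys, names(config))
  if (length(missing)) {
    stop(cmd, ": missing required config key(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Pipeline command: coupling trajectory
#'
#' Reads the donor/acceptor charge tables and the multi-frame XYZ ensemble
#' named in the config, computes one coupling record per frame, and writes
#' `records.csv`, a JSON run summary, and the resolved config to `out_dir`.
#'
#' Config keys: `donor_charges`, `acceptor_charges`, `trajectory` (paths);
#' `donor_idx`, `acceptor_idx` (1-based atom indices); optional `env_idx`,
#' `cutoff` (default 15 Angstrom), `polarizability_table` (path),
#' `replica_id`, `solver`, `thole_a`, `out_dir`.
#'
#' @param config named list or YAML path (see [resolve_config()]).
#' @param overrides named list of config overrides.
#' @return The coupling-record data frame, invisibly.
#' @export
cmd_couple <- function(config, overrides = list()) {
  config <- resolve_config(config, overrides)
  require_keys(config, c("donor_charges", "acceptor_charges", "trajectory",
                         "donor_idx", "acceptor_idx", "out_dir"),
               "couple")
  for (key in c("donor_charges", "acceptor_charges", "trajectory")) {
    if (!file.exists(config[[key]])) {
      stop("couple: input file not found: ", config[[key]], " (", key, ")")
    }
  }
  alpha <- if (!is.null(config$polarizability_table)) {
    load_polarizability_table(config$polarizability_table)
  } else default_polarizabilities()
  donor_cs <- load_charge_table(config$donor_charges, state_label = "D")
  acceptor_cs <- load_charge_table(config$acceptor_charges, state_label = "A")
  frames <- read_xyz_frames(config$trajectory,
                            stride_ps = config$stride_ps %||% 50)
  records <- coupling_trajectory(
    donor_cs, acceptor_cs, frames,
    donor_idx = as.integer(unlist(config$donor_idx)),
    acceptor_idx = as.integer(unlist(config$acceptor_idx)),
    cutoff = config$cutoff %||% 15,
    alpha_table = alpha,
    env_idx = if (!is.null(config$env_idx)) as.integer(unlist(config$env_idx)),
    replica_id = config$replica_id %||% "r1",
    solver = config$solver %||% "direct",
    thole_a = config$thole_a %||% 0)
  write_run_metadata(config, config$out_dir)
  write_coupling_records(records, file.path(config$out_dir, "records.csv"))
  summary <- list(
    n_frames = nrow(records),
    n_flagged = sum(records$flags != ""),
    mean_R_ang = mean(records$R_ang),
    mean_s = mean(records$s, na.rm = TRUE),
    mean_kappa2 = mean(records$kappa2))
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(records)
}

#' Pipeline command: efficiency distribution and distance bias
#'
#' Turns coupling records into instantaneous rates, a disorder-resolved
#' efficiency distribution, a histogram table, and the Forster distance-bias
#' comparison against the center distances recorded in the trajectory.
#'
#' Config keys: `tau_d_ns`, `r0_ang`, `mu_d_mag`, `mu_a_mag`; optional
#' `n_refr` (default sqrt(2)), `fast_window_ns` (default tau_d),
#' `stride_ps`, `n_bins`, `records` (CSV path, if `records` argument
#' absent), `out_dir`.
#'
#' @param config named list or YAML path.
#' @param records optional coupling-record data frame (else read from
#'   `config$records`).
#' @param overrides named list of config overrides.
#' @return List with `distribution`, `histogram`, `bias`, invisibly.
#' @export
cmd_efficiency <- function(config, records = NULL, overrides = list()) {
  config <- resolve_config(config, overrides)
  require_keys(config, c("tau_d_ns", "r0_ang", "mu_d_mag", "mu_a_mag",
                         "out_dir"), "efficiency")
  if (is.null(records)) {
    if (is.null(config$records)) stop("efficiency: no coupling records given")
    records <- read_coupling_records(config$records)
  }
  if (nrow(records) == 0) stop("efficiency: empty coupling records")
  p <- photophysics(config$tau_d_ns, config$r0_ang,
                    n_refr = config$n_refr %||% sqrt(2),
                    mu_d_mag = config$mu_d_mag, mu_a_mag = config$mu_a_mag)
  stride <- config$stride_ps %||% 50
  series <- split(instantaneous_rate(records$v_total, p), records$replica_id)
  dist <- efficiency_distribution(
    series, p, fast_window_ns = config$fast_window_ns %||% p$tau_d_ns,
    stride_ps = stride,
    source = list(replicas = names(series)))
  hist <- efficiency_histogram(dist, n_bins = config$n_bins %||% 50)
  bias <- tryCatch(distance_bias_analysis(dist, p$r0_ang, records$R_ang),
                   error = function(e) NULL)
  write_run_metadata(config, config$out_dir)
  utils::write.csv(hist, file.path(config$out_dir, "efficiency_histogram.csv"),
                   row.names = FALSE)
  report <- list(mean_e = dist$mean_e, n_windows = dist$n_windows,
                 window_duration_ns = dist$window_duration_ns,
                 distance_bias = if (!is.null(bias)) as.list(bias$summary))
  jsonlite::write_json(report, file.path(config$out_dir, "efficiency.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(distribution = dist, histogram = hist, bias = bias))
}

#' Pipeline command: titration fit
#'
#' Reads a titration CSV, applies the inner-filter correction, fits the
#' log-log binding model, corrects efficiencies by the fraction bound, and
#' writes a JSON report.
#'
#' Config keys: `titration` (CSV path, unless `series` is given), optional
#' `apply_ife` (default TRUE), `kd_uM`/`n_hill` (override the fitted
#' isotherm for the fraction-bound correction), `out_dir`.
#'
#' @param config named list or YAML path.
#' @param series optional `titration_series` (else read from
#'   `config$titration`).
#' @param overrides named list of config overrides.
#' @return The completed `binding_fit`, invisibly.
#' @export
cmd_titrate <- function(config, series = NULL, overrides = list()) {
  config <- resolve_config(config, overrides)
  require_keys(config, "out_dir", "titrate")
  if (is.null(series)) {
    if (is.null(config$titration)) stop("titrate: no titration input given")
    if (!file.exists(config$titration)) {
      stop("titrate: input file not found: ", config$titration)
    }
    series <- read_titration(config$titration)
  }
  fit <- hill_fit(series, apply_ife = config$apply_ife %||% TRUE)
  fit <- corrected_efficiency(series, fit,
                              kd_uM = config$kd_uM %||% fit$kd_uM,
                              n_hill = config$n_hill %||% fit$n_hill)
  write_run_metadata(config, config$out_dir)
  report <- list(ligand = series$ligand_id, log_kb = fit$log_kb,
                 n_hill = fit$n_hill, kd_uM = fit$kd_uM,
                 r_squared = fit$r_squared, e_final = fit$e_final,
                 n_clipped = fit$n_clipped,
                 per_conc = fit$per_conc)
  jsonlite::write_json(report, file.path(config$out_dir, "binding_fit.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(fit)
}

#' Pipeline command: rank binding sites
#'
#' Ranks simulated per-site mean efficiencies against the experimental
#' value and writes the ranking table.
#'
#' Config keys: `e_exp`, `site_means` (named list), optional `threshold`
#' (default 0.25), `out_dir`.
#'
#' @param config named list or YAML path.
#' @param overrides named list of config overrides.
#' @return The ranking data frame, invisibly.
#' @export
cmd_rank_sites <- function(config, overrides = list()) {
  config <- resolve_config(config, overrides)
  require_keys(config, c("e_exp", "site_means", "out_dir"), "rank-sites")
  ranking <- compare_to_simulation(config$e_exp,
                                   unlist(config$site_means),
                                   threshold = config$threshold %||% 0.25)
  write_run_metadata(config, config$out_dir)
  utils::write.csv(ranking, file.path(config$out_dir, "site_ranking.csv"),
                   row.names = FALSE)
  invisible(ranking)
}
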