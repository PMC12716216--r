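# Per-frame coupling records over a structural ensemble.

#' Compute a coupling trajectory over an ensemble of frames
#'
#' For every frame: carries the donor/acceptor transition charges onto the
#' frame coordinates, evaluates the bare Coulomb coupling, selects the
#' polarizable environment within the cutoff, solves the induced-dipole
#' equations for the field of the acceptor charges, evaluates the
#' environment term and the screening factor, and records the instantaneous
#' point-dipole quantities (center distance R, signed kappa, kappa^2, the
#' unscreened PDA coupling from the instantaneous transition dipoles).
#'
#' Frames whose |V_Coul| falls below `near_zero` Hartree get the
#' `near-zero-coulomb` flag: their screening factor and PDA/TrESP ratio are
#' undefined and profile functions exclude them from statistics while the
#' raw record is retained.
#'
#' @param donor_cs,acceptor_cs `transition_charge_set` objects.
#' @param frames list of `geometry_frame`s (e.g. from [read_xyz_frames()]).
#' @param donor_idx,acceptor_idx atom indices of the two chromophores in each
#'   frame (same order as the charge sets).
#' @param cutoff environment cutoff in Angstrom (default 15); atoms of any
#'   type within this distance of any chromophore atom are polarizable.
#' @param alpha_table named polarizability lookup in bohr^3.
#' @param env_idx candidate environment atoms (default: all others).
#' @param replica_id label stored with every record.
#' @param near_zero near-zero-Coulomb threshold in Hartree (default 1e-9).
#' @param solver `"direct"` or `"iterative"` induced-dipole solver.
#' @param thole_a Thole damping factor (0 = undamped).
#' @return A data frame with one row per frame: `frame_time`, `replica_id`,
#'   `v_coul`, `v_env`, `v_total`, `v_pda_unscreened` (all Hartree, plus
#'   `*_cm` copies in wavenumbers), `s`, `R_ang`, `kappa`, `kappa2`,
#'   `n_env_sites`, `flags`.
#' @export
coupling_trajectory <- function(donor_cs, acceptor_cs, frames,
                                donor_idx, acceptor_idx, cutoff = 15,
                                alpha_table = default_polarizabilities(),
                                env_idx = NULL, replica_id = "r1",
                                near_zero = 1e-9,
                                solver = c("direct", "iterative"),
                                thole_a = 0) {
  solver <- match.arg(solver)
  if (length(frames) == 0) stop("empty trajectory: no frames")
  if (inherits(frames, "geometry_frame")) frames <- list(frames)
  rows <- lapply(frames, function(fr) {
    dpc <- position_charges(donor_cs, fr$coords[donor_idx, , drop = FALSE])
    apc <- position_charges(acceptor_cs, fr$coords[acceptor_idx, , drop = FALSE])
    coupling_record(dpc, apc, frame = fr, donor_idx = donor_idx,
                    acceptor_idx = acceptor_idx, cutoff = cutoff,
                    alpha_table = alpha_table, env_idx = env_idx,
                    replica_id = replica_id, near_zero = near_zero,
                    solver = solver, thole_a = thole_a,
                    frame_time = fr$time_ps)
  })
  do.call(rbind, rows)
}

#' Compute one coupling record
#'
#' Single-frame building block of [coupling_trajectory()]; can also be used
#' directly with pre-built positioned charges and an explicit environment.
#'
#' @param donor_pc,acceptor_pc `positioned_charges` for this frame.
#' @param sites optional `polarizable_sites`; if `NULL` and a `frame` is
#'   given, the environment is selected by cutoff, otherwise the environment
#'   is empty (V_env = 0, s = 1).
#' @param frame optional `geometry_frame` for environment selection.
#' @inheritParams coupling_trajectory
#' @param frame_time time stamp stored in the record (ps).
#' @return One-row data frame (see [coupling_trajectory()]).
#' @export
coupling_record <- function(donor_pc, acceptor_pc, sites = NULL, frame = NULL,
                            donor_idx = NULL, acceptor_idx = NULL,
                            cutoff = 15,
                            alpha_table = default_polarizabilities(),
                            env_idx = NULL, replica_id = "r1",
                            near_zero = 1e-9,
                            solver = c("direct", "iterative"),
                            thole_a = 0, frame_time = 0) {
  solver <- match.arg(solver)
  if (is.null(sites)) {
    sites <- if (!is.null(frame)) {
      select_environment(frame, donor_idx, acceptor_idx, cutoff = cutoff,
                         alpha_table = alpha_table, env_idx = env_idx)
    } else polarizable_sites(numeric(0), numeric(0))
  }
  v_coul <- coulomb_coupling(donor_pc, acceptor_pc)
  if (nrow(sites$coords) > 0) {
    Ea <- field_at_sites(acceptor_pc, sites)
    sol <- solve_induced_dipoles(sites, Ea, method = solver,
                                 thole_a = thole_a)
    v_env <- env_coupling(donor_pc, sites, sol)
  } else {
    v_env <- 0
  }
  v_total <- v_coul + v_env
  flags <- character(1)
  if (abs(v_coul) < near_zero) flags <- "near-zero-coulomb"
  s <- screening_factor(v_coul, v_env, threshold = near_zero)
  mu_d <- transition_dipole(donor_pc)
  mu_a <- transition_dipole(acceptor_pc)
  rvec <- acceptor_pc$center - donor_pc$center
  R <- sqrt(sum(rvec^2))
  if (R <= 0) stop("coincident chromophore centers")
  kap <- kappa_factor(mu_d$components, mu_a$components, rvec)
  v_pda <- kap * mu_d$magnitude * mu_a$magnitude / (R * ANG2BOHR)^3
  data.frame(
    frame_time = frame_time, replica_id = replica_id,
    v_coul = v_coul, v_env = v_env, v_total = v_total,
    v_pda_unscreened = v_pda,
    v_coul_cm = hartree_to_cm(v_coul), v_env_cm = hartree_to_cm(v_env),
    v_total_cm = hartree_to_cm(v_total),
    v_pda_unscreened_cm = hartree_to_cm(v_pda),
    s = s, R_ang = R, kappa = kap, kappa2 = kap^2,
    n_env_sites = nrow(sites$coords),
    flags = flags,
    stringsAsFactors = FALSE)
}

#' Write / read coupling records as CSV
#'
#' @param records coupling-record data frame.
#' @param path file path.
#' @return `path` (write) or the records data frame (read).
#' @export
write_coupling_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_coupling_records
#' @export
read_coupling_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  rec$flags[is.na(rec$flags)] <- ""
  rec
}
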