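# Polarizable environment: site selection, induced-dipole solver, and the
# environment-mediated coupling term.
#
# Model: each environment atom within the cutoff carries an isotropic
# polarizability alpha and acquires an induced point dipole
#   mu_l = alpha_l ( E_l + sum_{m != l} T_lm mu_m )
# where E is the field of the acceptor's transition charges and T is the
# point dipole-dipole interaction tensor (optionally Thole-damped).  The
# environment term of the coupling is the interaction of those dipoles with
# the donor's transition-charge field, V_env = - sum_l mu_l . E_D(r_l).

#' Construct a set of polarizable sites
#'
#' @param coords n x 3 matrix of site coordinates in Angstrom.
#' @param alpha isotropic polarizabilities in bohr^3 (recycled if scalar);
#'   must be >= 0.
#' @param source_atom_id provenance labels (default running index).
#' @return An object of class `polarizable_sites`.
#' @export
polarizable_sites <- function(coords, alpha,
                              source_atom_id = NULL) {
  coords <- if (length(coords) == 0) {
    matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  } else as_coord_matrix(coords)
  n <- nrow(coords)
  alpha <- rep_len(as.numeric(alpha), n)
  if (n > 0 && any(alpha < 0)) stop("polarizabilities must be >= 0")
  if (is.null(source_atom_id)) source_atom_id <- as.character(seq_len(n))
  structure(list(coords = coords, alpha = alpha,
                 source_atom_id = rep_len(as.character(source_atom_id), n)),
            class = "polarizable_sites")
}

#' @export
print.polarizable_sites <- function(x, ...) {
  cat("Polarizable sites:", nrow(x$coords), "sites, alpha range [",
      if (nrow(x$coords)) paste(format(range(x$alpha), digits = 4),
                                collapse = ", ") else "",
      "] bohr^3\n")
  invisible(x)
}

#' Element-based polarizability defaults
#'
#' A small synthetic table of isotropic atomic polarizabilities (bohr^3)
#' keyed by element symbol, of the magnitude typical for additive polarizable
#' force fields.  Shipped so fixtures and examples run without an external
#' parameter file; production work should load the force-field table actually
#' used via [load_polarizability_table()].
#'
#' @return Named numeric vector (bohr^3).
#' @export
default_polarizabilities <- function() {
  c(H = 3.35, C = 9.01, N = 7.24, O = 5.65, S = 19.57, P = 12.2)
}

#' Read a polarizability assignment table
#'
#' Two-column plain text: atom type and polarizability.  Units default to
#' bohr^3; a comment line containing `units: ang3` switches to Angstrom^3
#' (converted on read).
#'
#' @param path file path.
#' @return Named numeric vector of polarizabilities in bohr^3.
#' @export
load_polarizability_table <- function(path) {
  lines <- readLines(path)
  ang3 <- any(grepl("units:\\s*ang3", lines, ignore.case = TRUE))
  keep <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(keep) == 0) stop("no data rows in ", path)
  tok <- strsplit(trimws(keep), "[,[:space:]]+")
  bad <- which(vapply(tok, length, integer(1)) != 2)
  if (length(bad)) stop("malformed polarizability row: '", keep[bad[1]], "'")
  vals <- as.numeric(vapply(tok, `[`, character(1), 2))
  if (anyNA(vals)) stop("non-numeric polarizability in ", path)
  names(vals) <- vapply(tok, `[`, character(1), 1)
  if (ang3) vals <- vals * ANG2BOHR^3
  vals
}

#' Select the polarizable environment within a cutoff
#'
#' Returns every environment atom whose distance to *any* donor or acceptor
#' atom is at most `cutoff` (closed interval), with polarizabilities attached
#' from the assignment table.  Donor and acceptor atoms themselves are never
#' part of the environment.  Optionally the selection can be extended to
#' whole residues (any atom of a residue within the cutoff pulls in the whole
#' residue).
#'
#' @param frame a `geometry_frame`.
#' @param donor_idx,acceptor_idx integer indices of chromophore atoms in the
#'   frame.
#' @param cutoff cutoff radius in Angstrom (default 15).
#' @param alpha_table named polarizability lookup (bohr^3) keyed by element /
#'   atom type, e.g. [default_polarizabilities()].
#' @param env_idx candidate environment atom indices; defaults to all frame
#'   atoms not in the chromophores.
#' @param residues optional per-atom residue labels (length = frame atoms);
#'   required when `whole_residue = TRUE`.
#' @param whole_residue logical; include complete residues instead of single
#'   atoms (default FALSE, atom-based truncation).
#' @return A `polarizable_sites` object (possibly empty).
#' @export
select_environment <- function(frame, donor_idx, acceptor_idx, cutoff = 15,
                               alpha_table = default_polarizabilities(),
                               env_idx = NULL, residues = NULL,
                               whole_residue = FALSE) {
  stopifnot(inherits(frame, "geometry_frame"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  chrom <- unique(c(donor_idx, acceptor_idx))
  if (is.null(env_idx)) env_idx <- setdiff(seq_len(nrow(frame$coords)), chrom)
  env_idx <- setdiff(env_idx, chrom)
  if (length(env_idx) == 0) return(polarizable_sites(numeric(0), numeric(0)))
  d <- cross_distances(frame$coords[env_idx, , drop = FALSE],
                       frame$coords[chrom, , drop = FALSE])
  mind <- apply(d, 1, min)
  within <- mind <= cutoff
  if (whole_residue) {
    if (is.null(residues)) stop("whole_residue = TRUE requires residue labels")
    res <- residues[env_idx]
    within <- res %in% unique(res[within])
  }
  sel <- env_idx[within]
  if (length(sel) == 0) return(polarizable_sites(numeric(0), numeric(0)))
  el <- frame$elements[sel]
  missing <- setdiff(unique(el), names(alpha_table))
  if (length(missing)) {
    stop("no polarizability assignment for atom type(s): ",
         paste(missing, collapse = ", "))
  }
  polarizable_sites(frame$coords[sel, , drop = FALSE],
                    unname(alpha_table[el]),
                    source_atom_id = as.character(sel))
}

#' Electric field of transition charges at polarizable sites
#'
#' E_l = sum_j q_j (r_l - r_j) / |r_l - r_j|^3 in atomic units (charges in e,
#' distances converted to bohr).
#'
#' @param charges a `positioned_charges` object (the field source).
#' @param sites a `polarizable_sites` object or an n x 3 coordinate matrix in
#'   Angstrom.
#' @param min_dist clash threshold in Angstrom (default 0.1).
#' @return n x 3 matrix of field vectors in atomic units (Hartree/(e*bohr)).
#' @export
field_at_sites <- function(charges, sites, min_dist = 0.1) {
  stopifnot(inherits(charges, "positioned_charges"))
  sc <- site_coords(sites)
  n <- nrow(sc)
  if (n == 0) return(matrix(numeric(0), 0, 3))
  d <- cross_distances(sc, charges$coords)           # n_sites x n_charges, Ang
  if (any(d < min_dist)) {
    stop("clash: site within ", min_dist, " Angstrom of a transition charge")
  }
  db <- d * ANG2BOHR
  w <- sweep(1 / db^3, 2, charges$charges, "*")       # q_j / r^3
  E <- matrix(0, n, 3)
  for (k in 1:3) {
    diff_k <- outer(sc[, k], charges$coords[, k], "-") * ANG2BOHR
    E[, k] <- rowSums(w * diff_k)
  }
  E
}

site_coords <- function(sites) {
  if (inherits(sites, "polarizable_sites")) sites$coords
  else if (length(sites) == 0) matrix(numeric(0), 0, 3)
  else as_coord_matrix(sites)
}

# Dense 3N x 3N dipole-dipole interaction matrix in atomic units.
# thole_a > 0 applies linear Thole damping with per-pair smearing length
# a * (alpha_l alpha_m)^(1/6).
dipole_tensor_matrix <- function(coords_ang, alpha, thole_a = 0) {
  n <- nrow(coords_ang)
  Tm <- matrix(0, 3 * n, 3 * n)
  if (n < 2) return(Tm)
  xb <- coords_ang * ANG2BOHR
  for (l in seq_len(n - 1)) {
    for (m in (l + 1):n) {
      rv <- xb[m, ] - xb[l, ]
      r <- sqrt(sum(rv^2))
      if (r < 1e-6) stop("coincident polarizable sites")
      l3 <- 1; l5 <- 1
      if (thole_a > 0 && alpha[l] > 0 && alpha[m] > 0) {
        v <- r / (thole_a * (alpha[l] * alpha[m])^(1 / 6))
        if (v < 1) { l3 <- 4 * v^3 - 3 * v^4; l5 <- v^4 }
      }
      blk <- (3 * l5 * tcrossprod(rv) / r^2 - l3 * diag(3)) / r^3
      ii <- (3 * l - 2):(3 * l)
      jj <- (3 * m - 2):(3 * m)
      Tm[ii, jj] <- blk
      Tm[jj, ii] <- blk
    }
  }
  Tm
}

#' Solve the mutually coupled induced-dipole equations
#'
#' Solves mu_l = alpha_l (E_l + sum_(m != l) T_lm mu_m) for all polarizable
#' sites.  `method = "direct"` assembles and solves the dense 3N x 3N linear
#' system (alpha^-1 - T) mu = E; `method = "iterative"` runs a damped
#' fixed-point (Jacobi) iteration with linear mixing.  Sites with alpha = 0
#' carry zero dipole and are removed from the system.
#'
#' @param sites a `polarizable_sites` object.
#' @param field n x 3 matrix of source fields at the sites (atomic units),
#'   e.g. from [field_at_sites()].
#' @param method `"direct"` or `"iterative"`.
#' @param tol iterative convergence tolerance on the maximum dipole component
#'   change, e*bohr (default 1e-10).
#' @param max_iter iteration cap (default 500).
#' @param mixing linear mixing parameter in (0, 1] (default 0.5).
#' @param thole_a linear Thole damping factor for the dipole-dipole tensor;
#'   0 (default) disables damping.
#' @return A list of class `induced_dipole_solution`: `dipoles` (n x 3,
#'   e*bohr), `residual_norm` (max abs residual of the fixed-point equation),
#'   `iterations`, `method`.
#' @export
solve_induced_dipoles <- function(sites, field,
                                  method = c("direct", "iterative"),
                                  tol = 1e-10, max_iter = 500L,
                                  mixing = 0.5, thole_a = 0) {
  method <- match.arg(method)
  stopifnot(inherits(sites, "polarizable_sites"))
  if (!is.numeric(tol) || tol <= 0) stop("tolerance must be > 0")
  n <- nrow(sites$coords)
  field <- if (n == 0) matrix(numeric(0), 0, 3) else as.matrix(field)
  if (nrow(field) != n) stop("field rows (", nrow(field),
                             ") do not match site count (", n, ")")
  mu <- matrix(0, n, 3)
  if (n == 0 || all(sites$alpha == 0)) {
    return(structure(list(dipoles = mu, residual_norm = 0, iterations = 0L,
                          method = method),
                     class = "induced_dipole_solution"))
  }
  act <- which(sites$alpha > 0)
  alpha <- sites$alpha[act]
  E <- field[act, , drop = FALSE]
  Tm <- dipole_tensor_matrix(sites$coords[act, , drop = FALSE], alpha, thole_a)
  na <- length(act)
  evec <- as.vector(t(E))                     # (x1,y1,z1,x2,...)
  ainv <- rep(1 / alpha, each = 3)
  iters <- 0L
  if (method == "direct") {
    A <- -Tm
    diag(A) <- diag(A) + ainv
    muv <- tryCatch(solve(A, evec),
                    error = function(e) stop("singular induced-dipole system: ",
                                             conditionMessage(e)))
  } else {
    muv <- evec / ainv                        # alpha * E start
    repeat {
      iters <- iters + 1L
      upd <- (evec + as.vector(Tm %*% muv)) / ainv
      delta <- max(abs(upd - muv))
      muv <- (1 - mixing) * muv + mixing * upd
      if (delta <= tol) break
      if (iters >= max_iter) {
        stop("induced-dipole iteration did not converge in ", max_iter,
             " steps; last max component change = ", format(delta, digits = 4),
             " e*bohr")
      }
    }
  }
  resid <- max(abs(muv - (evec + as.vector(Tm %*% muv)) / ainv))
  mu[act, ] <- matrix(muv, ncol = 3, byrow = TRUE)
  structure(list(dipoles = mu, residual_norm = resid, iterations = iters,
                 method = method),
            class = "induced_dipole_solution")
}

#' @export
print.induced_dipole_solution <- function(x, ...) {
  cat("Induced dipoles:", nrow(x$dipoles), "sites,", x$method,
      sprintf("solve, residual %.2e, %d iterations\n",
              x$residual_norm, x$iterations))
  invisible(x)
}

#' Environment-mediated coupling term
#'
#' Interaction of the donor's transition-charge field with the dipoles the
#' acceptor's transition charges induce in the environment:
#' V_env = - sum_l mu_l . E_D(r_l), in Hartree.  By linear response the
#' opposite convention (induce with the donor field, contract with the
#' acceptor field) gives the identical value; see the package tests.
#'
#' @param donor `positioned_charges` of the donor.
#' @param sites `polarizable_sites` used in the solve.
#' @param solution an `induced_dipole_solution` for the acceptor's field, or
#'   a bare n x 3 dipole matrix (e*bohr).
#' @return Energy in Hartree (0 for an empty environment).
#' @export
env_coupling <- function(donor, sites, solution) {
  mu <- if (inherits(solution, "induced_dipole_solution")) solution$dipoles
        else as.matrix(solution)
  sc <- site_coords(sites)
  if (nrow(sc) == 0) return(0)
  if (nrow(mu) != nrow(sc)) stop("dipole count does not match site count")
  Ed <- field_at_sites(donor, sc)
  -sum(Ed * mu)
}

#' Dielectric screening factor
#'
#' s = (V_Coul + V_env) / V_Coul, the ratio of the environment-dressed
#' coupling to the bare Coulomb coupling.  Forster theory approximates this
#' by 1/n^2.  Near a Coulomb node the ratio is ill-conditioned: when
#' |V_Coul| falls below `threshold` the function returns `NA` (callers flag
#' such frames and exclude them from statistics).
#'
#' @param v_coul,v_env couplings in Hartree.
#' @param threshold near-zero-Coulomb threshold in Hartree (default 1e-9).
#' @return Dimensionless screening factor, or `NA_real_` below threshold.
#' @export
screening_factor <- function(v_coul, v_env, threshold = 1e-9) {
  ifelse(abs(v_coul) < threshold, NA_real_, (v_coul + v_env) / v_coul)
}

#' Distance-binned screening profile
#'
#' Per-bin mean, standard deviation and count of the screening factor s as a
#' function of donor-acceptor center distance; frames flagged
#' `near-zero-coulomb` are excluded and counted in the `n_excluded`
#' attribute.  The Forster reference value 1/n^2 is attached as attribute
#' `forster_s` for plotting.
#'
#' @inheritParams pda_ratio_profile
#' @param n2 squared refractive index used for the reference line
#'   (default 2).
#' @return Binned data frame as in [pda_ratio_profile()].
#' @export
screening_profile <- function(records, bin_width = 1, n2 = 2) {
  out <- binned_profile(records, function(r) r$s, bin_width = bin_width)
  attr(out, "forster_s") <- 1 / n2
  out
}
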