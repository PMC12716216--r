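# Transition-charge representation of a chromophore excitation and its
# mapping onto per-frame geometries.

#' Construct a transition-charge set
#'
#' A transition-charge set represents one electronic excitation of a
#' chromophore by atom-centered charges fitted (externally) to reproduce the
#' electrostatic potential of the quantum-mechanical transition density
#' (TrESP charges).  Charges are anchored to a template geometry and can be
#' carried onto any structural frame with matching atom order via
#' [position_charges()].
#'
#' Transition charges integrate a transition density, so a physically valid
#' set is (near-)neutral; `net_tol` bounds the tolerated magnitude of the
#' charge sum.  The `scale` factor multiplies all charges uniformly, e.g. to
#' match a reference transition dipole (see [rescale_to_dipole()]).
#'
#' @param chromophore_id character label, e.g. `"Trp214"`.
#' @param state_label character label for the excited state, e.g. `"La"`.
#' @param elements character vector of element symbols, one per atom.
#' @param coords numeric matrix (n x 3) of template coordinates in Angstrom.
#' @param charges numeric vector of transition charges in elementary-charge
#'   units (before scaling).
#' @param scale positive scalar applied to all charges (default 1).
#' @param net_tol tolerance on `|sum(charges * scale)|` in e (default 1e-3).
#' @return An object of class `transition_charge_set`.
#' @seealso [load_charge_table()], [position_charges()], [transition_dipole()]
#' @export
transition_charge_set <- function(chromophore_id, state_label, elements,
                                  coords, charges, scale = 1,
                                  net_tol = 1e-3) {
  coords <- as_coord_matrix(coords)
  charges <- as.numeric(charges)
  if (nrow(coords) != length(charges)) {
    stop("number of charges (", length(charges),
         ") does not equal number of atoms (", nrow(coords), ")")
  }
  if (length(elements) != length(charges)) {
    stop("number of element symbols (", length(elements),
         ") does not equal number of charges (", length(charges), ")")
  }
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("scale must be a single positive number")
  }
  net <- abs(sum(charges * scale))
  if (net > net_tol) {
    stop("net transition charge ", format(net, digits = 6),
         " e exceeds tolerance ", net_tol,
         " e; transition charges must integrate a (neutral) transition density")
  }
  structure(
    list(chromophore_id = as.character(chromophore_id)[1],
         state_label = as.character(state_label)[1],
         elements = as.character(elements),
         coords = coords,
         charges = charges,
         scale = scale,
         net_tol = net_tol),
    class = "transition_charge_set")
}

#' @export
print.transition_charge_set <- function(x, ...) {
  cat("Transition charge set:", x$chromophore_id,
      sprintf("(state %s)\n", x$state_label))
  cat("  atoms:", length(x$charges),
      " scale:", format(x$scale, digits = 6),
      " net charge:", format(sum(x$charges * x$scale), digits = 3), "e\n")
  invisible(x)
}

#' Number of atoms in a charge set
#' @param cs a `transition_charge_set`.
#' @return integer atom count.
#' @export
n_atoms <- function(cs) length(cs$charges)

# coerce to an n x 3 numeric matrix
as_coord_matrix <- function(x) {
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != 3) {
    stop("coordinates must be an n x 3 matrix")
  }
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' Read a transition-charge table
#'
#' Parses a plain-text charge table with columns `element x y z q`
#' (coordinates in Angstrom, charges in e).  Fields may be separated by
#' whitespace and/or commas; lines starting with `#` are comments.  The net
#' charge is validated against `net_tol`: a violation is an error, never a
#' silent correction.
#'
#' @param path file path.
#' @inheritParams transition_charge_set
#' @return A [transition_charge_set()].
#' @export
load_charge_table <- function(path, chromophore_id = basename(path),
                              state_label = "S1", net_tol = 1e-3) {
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) stop("no data rows in ", path)
  el <- character(length(keep))
  num <- matrix(NA_real_, length(keep), 4)
  for (k in seq_along(keep)) {
    ln <- keep[k]
    tok <- strsplit(trimws(lines[ln]), "[,[:space:]]+")[[1]]
    if (length(tok) != 5) {
      stop("malformed row at line ", ln, " of ", path,
           ": expected 5 fields (element x y z q), found ", length(tok))
    }
    vals <- suppressWarnings(as.numeric(tok[2:5]))
    if (anyNA(vals)) {
      stop("malformed row at line ", ln, " of ", path,
           ": non-numeric coordinate or charge")
    }
    el[k] <- tok[1]
    num[k, ] <- vals
  }
  transition_charge_set(chromophore_id, state_label, el,
                        num[, 1:3, drop = FALSE], num[, 4],
                        net_tol = net_tol)
}

#' Write a transition-charge table
#'
#' Inverse of [load_charge_table()]; the *scaled* charges are written, so a
#' round trip preserves the effective charge set.
#'
#' @param cs a `transition_charge_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_charge_table <- function(cs, path) {
  stopifnot(inherits(cs, "transition_charge_set"))
  q <- cs$charges * cs$scale
  hdr <- sprintf("# transition charges: %s state %s (element x y z q; Angstrom, e)",
                 cs$chromophore_id, cs$state_label)
  rows <- sprintf("%-3s %s %s %s %s", cs$elements,
                  format_full(cs$coords[, 1]), format_full(cs$coords[, 2]),
                  format_full(cs$coords[, 3]), format_full(q))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# full-precision decimal formatting so tables round-trip bit-identically
format_full <- function(x) sprintf("%.17g", x)

#' Carry transition charges onto frame coordinates
#'
#' Maps the charges of a transition-charge set onto the coordinates of one
#' structural frame (same atoms, same order).  The chromophore center is the
#' unweighted centroid of the charge-bearing atoms; this is the point used
#' for center-to-center distances and for placing the point transition
#' dipole.
#'
#' @param cs a `transition_charge_set`.
#' @param coords n x 3 matrix of frame coordinates in Angstrom for the
#'   chromophore's atoms, in the same order as `cs`.
#' @return An object of class `positioned_charges` with fields `coords`
#'   (Angstrom), `charges` (e, scaling applied), `center` (Angstrom) and
#'   `chromophore_id`.
#' @export
position_charges <- function(cs, coords = cs$coords) {
  stopifnot(inherits(cs, "transition_charge_set"))
  coords <- as_coord_matrix(coords)
  if (nrow(coords) != n_atoms(cs)) {
    stop("atom-count mismatch: charge set has ", n_atoms(cs),
         " atoms but frame selection has ", nrow(coords))
  }
  positioned_charges(coords, cs$charges * cs$scale,
                     chromophore_id = cs$chromophore_id)
}

#' Construct positioned charges directly
#'
#' Low-level constructor pairing per-frame coordinates with charges; used by
#' [position_charges()] and by fixture generators.
#'
#' @param coords n x 3 matrix, Angstrom.
#' @param charges numeric vector, e.
#' @param center optional center point (Angstrom); defaults to the centroid.
#' @param chromophore_id optional label.
#' @return An object of class `positioned_charges`.
#' @export
positioned_charges <- function(coords, charges, center = NULL,
                               chromophore_id = "chromophore") {
  coords <- as_coord_matrix(coords)
  charges <- as.numeric(charges)
  if (nrow(coords) != length(charges)) {
    stop("coordinate count (", nrow(coords),
         ") does not equal charge count (", length(charges), ")")
  }
  if (is.null(center)) center <- colMeans(coords)
  center <- as.numeric(center)
  stopifnot(length(center) == 3)
  lo <- apply(coords, 2, min) - 1e-9
  hi <- apply(coords, 2, max) + 1e-9
  if (any(center < lo | center > hi)) {
    stop("center lies outside the bounding box of the coordinates")
  }
  structure(list(coords = coords, charges = charges, center = center,
                 chromophore_id = chromophore_id),
            class = "positioned_charges")
}

#' @export
print.positioned_charges <- function(x, ...) {
  cat("Positioned charges:", x$chromophore_id, "-", length(x$charges),
      "atoms, center (", paste(sprintf("%.3f", x$center), collapse = ", "),
      ") Angstrom\n")
  invisible(x)
}

#' Transition dipole of a positioned charge set
#'
#' Computes mu = sum_i q_i r_i, converted to atomic units (e*bohr).  For a
#' neutral charge set the dipole is origin-independent; a non-neutral set
#' (|sum q| above `net_tol`) triggers a warning and the origin is fixed at
#' the |q|-weighted center of the charges so the result is still
#' well-defined.
#'
#' @param pc a `positioned_charges` object.
#' @param net_tol neutrality tolerance in e (default 1e-3).
#' @return An object of class `transition_dipole` with `components` (e*bohr)
#'   and `magnitude` (their Euclidean norm).
#' @export
transition_dipole <- function(pc, net_tol = 1e-3) {
  stopifnot(inherits(pc, "positioned_charges"))
  q <- pc$charges
  coords <- pc$coords
  if (abs(sum(q)) > net_tol) {
    warning("charge set is not neutral (sum q = ", format(sum(q), digits = 4),
            " e); dipole evaluated about the |q|-weighted center")
    if (sum(abs(q)) > 0) {
      ctr <- colSums(coords * abs(q)) / sum(abs(q))
      coords <- sweep(coords, 2, ctr)
    }
  }
  mu_eA <- colSums(coords * q)
  transition_dipole_vector(mu_eA * ANG2BOHR)
}

#' Construct a transition dipole vector
#'
#' @param components numeric 3-vector in e*bohr.
#' @return An object of class `transition_dipole` with the components and
#'   their norm.
#' @export
transition_dipole_vector <- function(components) {
  components <- as.numeric(components)
  stopifnot(length(components) == 3)
  structure(list(components = components,
                 magnitude = sqrt(sum(components^2))),
            class = "transition_dipole")
}

#' @export
print.transition_dipole <- function(x, ...) {
  cat(sprintf("Transition dipole: (%.6g, %.6g, %.6g) e*bohr, |mu| = %.6g\n",
              x$components[1], x$components[2], x$components[3], x$magnitude))
  invisible(x)
}

#' Rescale a charge set to a target transition dipole magnitude
#'
#' Adjusts the uniform `scale` factor so that the transition dipole evaluated
#' on the template (or supplied) geometry has the requested magnitude.  This
#' is the standard way to make an ESP-fitted charge set reproduce a reference
#' quantum-mechanical transition dipole.
#'
#' @param cs a `transition_charge_set`.
#' @param target_magnitude target dipole magnitude in e*bohr (> 0).
#' @param coords geometry on which the dipole is evaluated; defaults to the
#'   template coordinates.
#' @return A rescaled `transition_charge_set`.
#' @export
rescale_to_dipole <- function(cs, target_magnitude, coords = cs$coords) {
  stopifnot(inherits(cs, "transition_charge_set"))
  if (!is.numeric(target_magnitude) || target_magnitude <= 0) {
    stop("target_magnitude must be positive")
  }
  cur <- transition_dipole(position_charges(cs, coords))$magnitude
  if (cur <= 0) stop("current transition dipole is zero; cannot rescale")
  out <- cs
  out$scale <- cs$scale * target_magnitude / cur
  # re-validate neutrality under the new scale
  net <- abs(sum(out$charges * out$scale))
  if (net > out$net_tol) {
    stop("rescaling pushes net charge (", format(net, digits = 6),
         " e) beyond tolerance ", out$net_tol, " e")
  }
  out
}
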