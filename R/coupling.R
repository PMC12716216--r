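# Donor-acceptor electronic couplings: transition-charge Coulomb sums,
# point-dipole couplings, and the orientation factor kappa^2.

#' Coulomb coupling between two transition-charge distributions
#'
#' Evaluates the bare Coulomb interaction between donor and acceptor
#' transition charges, V = sum_ij q_i q_j / |r_i - r_j|, in Hartree
#' (distances converted to bohr internally).  This is the atomistic
#' counterpart of the point-dipole coupling and captures the full shape of
#' both transition densities.
#'
#' @param donor,acceptor `positioned_charges` objects.
#' @param min_dist minimum tolerated interatomic donor-acceptor distance in
#'   Angstrom (default 0.1); closer pairs indicate a steric clash and raise
#'   an error, since such frames should be excluded upstream.
#' @return Coupling in Hartree (signed; the overall sign follows the
#'   arbitrary sign of the transition charges).
#' @export
coulomb_coupling <- function(donor, acceptor, min_dist = 0.1) {
  stopifnot(inherits(donor, "positioned_charges"),
            inherits(acceptor, "positioned_charges"))
  d <- cross_distances(donor$coords, acceptor$coords)
  if (any(d < min_dist)) {
    stop("steric clash: minimum donor-acceptor atom distance ",
         format(min(d), digits = 3), " Angstrom < ", min_dist,
         " Angstrom; exclude this frame upstream")
  }
  sum(outer(donor$charges, acceptor$charges) / (d * ANG2BOHR))
}

# all-pairs Euclidean distances between two coordinate sets (Angstrom)
cross_distances <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Orientation factor kappa and kappa squared
#'
#' `kappa_factor()` returns the signed dipole-dipole orientation factor
#' kappa = mu_d . mu_a - 3 (mu_d . r)(mu_a . r) for unit vectors;
#' `kappa_squared()` returns its square, which lies in \[0, 4\] and averages
#' to 2/3 over isotropic orientations.  Inputs are renormalized internally;
#' a vector with norm below 1e-8 is an error.
#'
#' @param mu_d_hat,mu_a_hat donor/acceptor transition-dipole direction
#'   3-vectors (need not be unit length).
#' @param r_hat donor-to-acceptor axis 3-vector.
#' @return `kappa_factor()`: signed kappa; `kappa_squared()`: kappa^2.
#' @examples
#' kappa_squared(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1))  # collinear: 4
#' kappa_squared(c(1, 0, 0), c(1, 0, 0), c(0, 0, 1))  # parallel, perp axis: 1
#' @export
kappa_factor <- function(mu_d_hat, mu_a_hat, r_hat) {
  d <- unit_vector(mu_d_hat, "mu_d_hat")
  a <- unit_vector(mu_a_hat, "mu_a_hat")
  r <- unit_vector(r_hat, "r_hat")
  sum(d * a) - 3 * sum(d * r) * sum(a * r)
}

#' @rdname kappa_factor
#' @export
kappa_squared <- function(mu_d_hat, mu_a_hat, r_hat) {
  kappa_factor(mu_d_hat, mu_a_hat, r_hat)^2
}

unit_vector <- function(v, name = "vector") {
  v <- as.numeric(v)
  stopifnot(length(v) == 3)
  nrm <- sqrt(sum(v^2))
  if (nrm < 1e-8) stop(name, " has near-zero norm; cannot normalize")
  v / nrm
}

# vectorized kappa^2 over matrices of row vectors (assumed unit rows)
kappa_squared_rows <- function(d, a, r) {
  (rowSums(d * a) - 3 * rowSums(d * r) * rowSums(a * r))^2
}

#' Point-dipole (PDA) coupling
#'
#' Forster point-dipole coupling V = s * kappa * |mu_D| |mu_A| / R^3 in
#' Hartree, with the center-to-center distance R in bohr.  With
#' `screening = 1` this is the unscreened PDA coupling used in ratio
#' analyses against the transition-charge Coulomb term; the Forster choice
#' is `screening = 1/n^2`.
#'
#' @param mu_d,mu_a `transition_dipole` objects or numeric 3-vectors in
#'   e*bohr.
#' @param center_d,center_a chromophore centers in Angstrom.
#' @param screening dimensionless screening factor (default 1, unscreened).
#' @return Signed coupling in Hartree.
#' @export
pda_coupling <- function(mu_d, mu_a, center_d, center_a, screening = 1) {
  mu_d <- dipole_components(mu_d)
  mu_a <- dipole_components(mu_a)
  rvec <- as.numeric(center_a) - as.numeric(center_d)
  R <- sqrt(sum(rvec^2))
  if (R <= 0) stop("coincident chromophore centers: R = 0")
  k <- kappa_factor(mu_d, mu_a, rvec)
  screening * k * sqrt(sum(mu_d^2)) * sqrt(sum(mu_a^2)) / (R * ANG2BOHR)^3
}

dipole_components <- function(mu) {
  if (inherits(mu, "transition_dipole")) mu$components else as.numeric(mu)
}

#' Distance-binned profile of the PDA/TrESP coupling ratio
#'
#' Bins per-frame ratios V_PDA / V_Coul (both unscreened) by donor-acceptor
#' center distance and reports per-bin mean, standard deviation and count.
#' Frames flagged `near-zero-coulomb` are excluded from the statistics (the
#' ratio is undefined at Coulomb nodes) and counted separately.
#'
#' @param records a coupling-record data frame (see [coupling_trajectory()])
#'   with columns `R_ang`, `v_pda_unscreened`, `v_coul` and `flags`.
#' @param bin_width bin width in Angstrom (default 1).
#' @return A data frame with `bin_center`, `mean`, `sd`, `n`, plus attribute
#'   `n_excluded` (flagged records).
#' @export
pda_ratio_profile <- function(records, bin_width = 1) {
  binned_profile(records, function(r) r$v_pda_unscreened / r$v_coul,
                 bin_width = bin_width)
}

# shared binning machinery for ratio and screening profiles
binned_profile <- function(records, value_fun, bin_width = 1) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("empty coupling-record input")
  }
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin width must be > 0")
  flagged <- grepl("near-zero-coulomb", records$flags %||% "")
  use <- records[!flagged, , drop = FALSE]
  if (nrow(use) == 0) {
    stop("all ", nrow(records), " records carry the near-zero-coulomb flag; ",
         "no usable frames")
  }
  val <- value_fun(use)
  bin <- floor(use$R_ang / bin_width)
  agg <- split(val, bin)
  centers <- (as.numeric(names(agg)) + 0.5) * bin_width
  out <- data.frame(
    bin_center = centers,
    mean = vapply(agg, mean, numeric(1)),
    sd = vapply(agg, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                numeric(1)),
    n = vapply(agg, length, integer(1)),
    row.names = NULL)
  out <- out[order(out$bin_center), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(flagged)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
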