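# Synthetic fixture generators with analytic ground truth.  Every generator
# is a pure function of (seed, parameters); the ground truth it ships is
# computed from closed forms, independent of the analysis pipeline.

# run expr with a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Dipole-pair fixture with exact Coulomb and point-dipole couplings
#'
#' Builds two minimal chromophores, each a +q/-q charge pair with
#' q * separation = `mu_mag`, the donor centered at the origin and the
#' acceptor at distance `r_ang` along the z axis.  Because both couplings
#' have closed forms for this geometry, the fixture carries its own ground
#' truth: the exact 4-term Coulomb sum and the exact point-dipole value.
#' As `r_ang` grows relative to `sep_ang` the two must converge, which is
#' the classic test of the point-dipole approximation.
#'
#' @param mu_mag transition-dipole magnitude in e*bohr (0 gives zero
#'   charges).
#' @param sep_ang intramolecular +/- charge separation in Angstrom.
#' @param r_ang center-to-center distance in Angstrom (> `sep_ang`).
#' @param orientation `"collinear"` (both dipoles along the axis,
#'   kappa = -2), `"parallel"` (both perpendicular to the axis, kappa = 1),
#'   `"orthogonal_null"` (donor along the axis, acceptor perpendicular,
#'   kappa = 0), or `"custom"` with explicit `dir_d`, `dir_a`.
#' @param dir_d,dir_a dipole direction 3-vectors for `orientation =
#'   "custom"`.
#' @return A list: `donor`, `acceptor` (`positioned_charges`), `mu_d`,
#'   `mu_a` (e*bohr 3-vectors), `kappa`, `v_pda` and `v_coul` (exact ground
#'   truth, Hartree), `r_ang`, `sep_ang`.
#' @export
make_dipole_pair <- function(mu_mag, sep_ang, r_ang,
                             orientation = c("collinear", "parallel",
                                             "orthogonal_null", "custom"),
                             dir_d = NULL, dir_a = NULL) {
  orientation <- match.arg(orientation)
  if (r_ang <= sep_ang) {
    stop("center distance (", r_ang, " A) must exceed the charge separation (",
         sep_ang, " A)")
  }
  dirs <- switch(orientation,
    collinear = list(d = c(0, 0, 1), a = c(0, 0, 1)),
    parallel = list(d = c(1, 0, 0), a = c(1, 0, 0)),
    orthogonal_null = list(d = c(0, 0, 1), a = c(1, 0, 0)),
    custom = {
      if (is.null(dir_d) || is.null(dir_a)) {
        stop("custom orientation requires dir_d and dir_a")
      }
      list(d = unit_vector(dir_d), a = unit_vector(dir_a))
    })
  ud <- unit_vector(dirs$d); ua <- unit_vector(dirs$a)
  q <- if (mu_mag == 0) 0 else mu_mag / (sep_ang * ANG2BOHR)
  ctr_a <- c(0, 0, r_ang)
  coords_d <- rbind(+ud * sep_ang / 2, -ud * sep_ang / 2)
  coords_a <- rbind(ctr_a + ua * sep_ang / 2, ctr_a - ua * sep_ang / 2)
  donor <- positioned_charges(coords_d, c(q, -q), chromophore_id = "donor")
  acceptor <- positioned_charges(coords_a, c(q, -q),
                                 chromophore_id = "acceptor")
  # ground truth, written out explicitly (independent of the pipeline code)
  kap <- sum(ud * ua) - 3 * ud[3] * ua[3]
  v_pda <- kap * mu_mag^2 / (r_ang * ANG2BOHR)^3
  v_coul <- 0
  for (i in 1:2) for (j in 1:2) {
    rij <- sqrt(sum((coords_d[i, ] - coords_a[j, ])^2)) * ANG2BOHR
    v_coul <- v_coul + donor$charges[i] * acceptor$charges[j] / rij
  }
  list(donor = donor, acceptor = acceptor,
       mu_d = ud * mu_mag, mu_a = ua * mu_mag,
       kappa = kap, v_pda = v_pda, v_coul = v_coul,
       r_ang = r_ang, sep_ang = sep_ang)
}

#' Isotropic orientation samples
#'
#' Draws `count` independent triples of unit vectors (donor dipole, acceptor
#' dipole, separation axis) uniformly on the sphere.  Over such triples the
#' orientation factor kappa^2 averages to 2/3.
#'
#' @param count number of triples (> 0).
#' @param seed RNG seed (the caller's RNG state is untouched).
#' @return A list of three `count` x 3 matrices with unit rows: `mu_d_hat`,
#'   `mu_a_hat`, `r_hat`.
#' @export
make_orientation_samples <- function(count, seed = 1) {
  stopifnot(count > 0)
  with_seed(seed, {
    draw <- function() {
      m <- matrix(stats::rnorm(3 * count), count, 3)
      m / sqrt(rowSums(m^2))
    }
    list(mu_d_hat = draw(), mu_a_hat = draw(), r_hat = draw())
  })
}

#' Two-timescale coupling trajectory with analytic efficiency
#'
#' Emulates the separation of static and dynamic disorder in a coupling
#' trajectory: a piecewise-constant slow component (one state per window of
#' `frames_per_window` frames, drawn from `slow_states` with `weights`) plus
#' additive zero-mean Gaussian fast noise of width `fast_sigma`.  Because
#' rates are quadratic in the coupling, Gaussian fast noise shifts the
#' window-averaged squared coupling by exactly `fast_sigma^2`, so the
#' intermediate-regime efficiency has the closed form evaluated by
#' [two_timescale_truth()].
#'
#' @param slow_states numeric vector of slow coupling values (Hartree).
#' @param weights sampling probabilities (default uniform).
#' @param fast_sigma Gaussian fast-noise width (Hartree, >= 0).
#' @param n_windows number of slow windows.
#' @param frames_per_window frames per window.
#' @param stride_ps frame spacing in ps (default 50).
#' @param seed RNG seed.
#' @return A list: `coupling` (length `n_windows * frames_per_window`),
#'   `state_seq` (slow value per window), `fast_sigma`, `stride_ps`,
#'   `frames_per_window`.
#' @export
make_two_timescale_trajectory <- function(slow_states, weights = NULL,
                                          fast_sigma = 0, n_windows = 10,
                                          frames_per_window = 20,
                                          stride_ps = 50, seed = 1) {
  stopifnot(length(slow_states) >= 1, fast_sigma >= 0)
  if (is.null(weights)) weights <- rep(1, length(slow_states))
  with_seed(seed, {
    state_seq <- sample(slow_states, n_windows, replace = TRUE,
                        prob = weights)
    v <- rep(state_seq, each = frames_per_window)
    if (fast_sigma > 0) v <- v + stats::rnorm(length(v), sd = fast_sigma)
    list(coupling = v, state_seq = state_seq, fast_sigma = fast_sigma,
         stride_ps = stride_ps, frames_per_window = frames_per_window)
  })
}

#' Analytic efficiency for a two-timescale fixture
#'
#' Closed-form intermediate-regime efficiency of a
#' [make_two_timescale_trajectory()] realization: per window,
#' tau <k>_fast = C (V_s^2 + sigma^2) with C the dimensionless rate
#' prefactor, and the efficiency distribution mean is the average of
#' E_w = tau<k>/(1 + tau<k>) over the realized windows.  (The expectation of
#' the window-mean squared noise is sigma^2 exactly; the residual
#' Monte-Carlo fluctuation of a pipeline estimate around this truth scales
#' as 1/sqrt(frames_per_window).)
#'
#' @param fixture result of [make_two_timescale_trajectory()].
#' @param p a [photophysics()] object.
#' @return The analytic mean efficiency.
#' @export
two_timescale_truth <- function(fixture, p) {
  stopifnot(inherits(p, "photophysics"))
  ktau <- rate_prefactor(p) * (fixture$state_seq^2 + fixture$fast_sigma^2)
  mean(ktau / (1 + ktau))
}

#' Synthetic fluorescence titration with known ground truth
#'
#' Generates a quenching titration from known binding parameters and bound-
#' complex efficiency.  Two generating models are available:
#' `"hill_quench"` (default) quenches the bound protein fraction,
#' I_DA = I_D (1 - e_true f(\[L\])) with the Hill isotherm
#' f = \[L\]^n / (K_d^n + \[L\]^n); `"loglinear"` makes the quenching ratio
#' (I_D - I_DA)/I_DA an exact power law (1/K_d) \[L\]^n (the log-log binding
#' model, exactly recoverable by [hill_fit()]; its implied bound-complex
#' efficiency is 1, so `e_true` must be 1 in this model).  Ligand
#' absorbances grow linearly with concentration and the emitted intensities
#' are attenuated accordingly, so the inner-filter correction is exercised
#' end to end.  Optional multiplicative log-normal noise.
#'
#' @param kd_uM dissociation constant in micromolar.
#' @param n_hill Hill coefficient.
#' @param e_true FRET efficiency of the bound complex, in (0, 1\].
#' @param i_d donor-only intensity (arbitrary units).
#' @param concs_uM nonzero ligand concentrations (default 10, 50, 100 uM).
#' @param noise_sigma multiplicative log-normal noise s.d. (0 = noiseless).
#' @param seed RNG seed.
#' @param model generating model, see above.
#' @param abs_ex_per_uM,abs_em_per_uM ligand absorbance per micromolar at
#'   the excitation / emission wavelength.
#' @return A [titration_series()] with attribute `ground_truth` (list of
#'   the generating parameters).
#' @export
make_titration <- function(kd_uM, n_hill, e_true, i_d = 1000,
                           concs_uM = c(10, 50, 100), noise_sigma = 0,
                           seed = 1, model = c("hill_quench", "loglinear"),
                           abs_ex_per_uM = 2e-3, abs_em_per_uM = 1e-3) {
  model <- match.arg(model)
  stopifnot(kd_uM > 0, n_hill > 0, e_true > 0, e_true <= 1, i_d > 0,
            all(concs_uM > 0))
  if (model == "loglinear" && e_true != 1) {
    stop("the log-linear generating model implies complete quenching of the ",
         "bound complex; use e_true = 1 (or the hill_quench model)")
  }
  f <- switch(model,
    hill_quench = concs_uM^n_hill / (kd_uM^n_hill + concs_uM^n_hill),
    loglinear = {
      ratio <- concs_uM^n_hill / kd_uM
      ratio / (1 + ratio)
    })
  ida <- i_d * (1 - e_true * f)
  if (noise_sigma > 0) {
    ida <- with_seed(seed, ida * exp(stats::rnorm(length(ida),
                                                  sd = noise_sigma)))
  }
  abs_ex <- abs_ex_per_uM * concs_uM
  abs_em <- abs_em_per_uM * concs_uM
  measured <- ida * 10^(-(abs_ex + abs_em) / 2)
  out <- titration_series(
    sprintf("synthetic-%s", model),
    conc_uM = c(0, concs_uM), intensity = c(i_d, measured),
    abs_ex = c(0, abs_ex), abs_em = c(0, abs_em))
  attr(out, "ground_truth") <- list(kd_uM = kd_uM, n_hill = n_hill,
                                    e_true = e_true, model = model,
                                    fraction_bound = f,
                                    noise_sigma = noise_sigma, seed = seed)
  out
}

#' Spherical shell of polarizable sites
#'
#' Places `n_sites` polarizable sites uniformly on a sphere around a center
#' point (by default the midpoint between donor and acceptor in the
#' dipole-pair fixtures).
#'
#' @param n_sites number of sites (>= 0).
#' @param radius_ang shell radius in Angstrom.
#' @param alpha isotropic polarizability per site, bohr^3.
#' @param center 3-vector shell center in Angstrom.
#' @param seed RNG seed.
#' @return A `polarizable_sites` object.
#' @export
make_polarizable_shell <- function(n_sites, radius_ang, alpha,
                                   center = c(0, 0, 0), seed = 1) {
  stopifnot(n_sites >= 0)
  if (n_sites == 0) return(polarizable_sites(numeric(0), numeric(0)))
  dirs <- with_seed(seed, {
    m <- matrix(stats::rnorm(3 * n_sites), n_sites, 3)
    m / sqrt(rowSums(m^2))
  })
  coords <- sweep(dirs * radius_ang, 2, center, "+")
  polarizable_sites(coords, alpha)
}
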