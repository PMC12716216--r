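# Fluorescence titration processing: inner-filter correction, Hill binding
# fit, fraction-bound-corrected FRET efficiencies, and ranking of simulated
# binding models against the experimental efficiency.

#' Construct a titration series
#'
#' Holds one fluorescence quenching titration: donor (protein) intensity at
#' a fixed emission wavelength as a function of ligand concentration, with
#' the ligand absorbances at the excitation and emission wavelengths needed
#' for inner-filter correction.  The zero-concentration point anchors the
#' donor-only intensity `i_d` and is never fitted.
#'
#' @param ligand_id character label.
#' @param conc_uM ligand concentrations in micromolar, strictly increasing;
#'   may include a leading 0 whose intensity then defines `i_d`.
#' @param intensity measured intensities (arbitrary units, > 0), same length
#'   as `conc_uM`.
#' @param abs_ex,abs_em ligand absorbances at the excitation and emission
#'   wavelengths per concentration (>= 0); default 0 (no inner-filter
#'   correction).
#' @param i_d donor-only intensity; defaults to the intensity at
#'   concentration 0 (required if no zero point is present).
#' @param protein_conc_uM protein concentration in micromolar (metadata).
#' @param excitation_nm,emission_nm wavelengths (metadata).
#' @return An object of class `titration_series`; the stored `conc_uM`,
#'   `intensity`, `abs_ex`, `abs_em` cover the nonzero concentrations only.
#' @export
titration_series <- function(ligand_id, conc_uM, intensity,
                             abs_ex = 0, abs_em = 0, i_d = NULL,
                             protein_conc_uM = 5,
                             excitation_nm = 295, emission_nm = 334) {
  conc_uM <- as.numeric(conc_uM)
  intensity <- as.numeric(intensity)
  stopifnot(length(conc_uM) == length(intensity))
  abs_ex <- rep_len(as.numeric(abs_ex), length(conc_uM))
  abs_em <- rep_len(as.numeric(abs_em), length(conc_uM))
  if (any(diff(conc_uM) <= 0)) {
    stop("ligand concentrations must be strictly increasing")
  }
  if (any(intensity <= 0)) stop("intensities must be positive")
  if (any(abs_ex < 0) || any(abs_em < 0)) stop("absorbances must be >= 0")
  zero <- conc_uM == 0
  if (is.null(i_d)) {
    if (!any(zero)) {
      stop("no zero-concentration point and no explicit i_d: ",
           "the donor-only intensity is required")
    }
    i_d <- intensity[zero]
  }
  if (i_d <= 0) stop("donor-only intensity must be positive")
  structure(list(ligand_id = as.character(ligand_id)[1],
                 protein_conc_uM = protein_conc_uM,
                 conc_uM = conc_uM[!zero],
                 intensity = intensity[!zero],
                 abs_ex = abs_ex[!zero], abs_em = abs_em[!zero],
                 i_d = i_d,
                 excitation_nm = excitation_nm, emission_nm = emission_nm),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration: %s, [P] = %g uM, %d ligand concentrations (%s uM)\n",
              x$ligand_id, x$protein_conc_uM, length(x$conc_uM),
              paste(x$conc_uM, collapse = ", ")))
  invisible(x)
}

#' Read a titration CSV
#'
#' Columns `ligand_conc_uM`, `intensity` and optionally `abs_ex`, `abs_em`;
#' a row with concentration 0 supplies the donor-only intensity.
#'
#' @param path file path.
#' @param ligand_id label (defaults to the file name).
#' @param ... passed to [titration_series()].
#' @return A `titration_series`.
#' @export
read_titration <- function(path, ligand_id = basename(path), ...) {
  tab <- utils::read.csv(path, comment.char = "#")
  need <- c("ligand_conc_uM", "intensity")
  if (!all(need %in% names(tab))) {
    stop("titration file must have columns ", paste(need, collapse = ", "))
  }
  titration_series(ligand_id, tab$ligand_conc_uM, tab$intensity,
                   abs_ex = tab$abs_ex %||% 0, abs_em = tab$abs_em %||% 0,
                   ...)
}

#' Inner-filter effect correction
#'
#' I_cor = I * 10^((Abs_ex + Abs_em) / 2): undoes the attenuation of the
#' excitation beam and of the emitted light by the absorbing ligand in the
#' cuvette.  Monotone increasing in both absorbances; the identity when both
#' are 0.
#'
#' @param intensity measured intensity (vectorized).
#' @param abs_ex,abs_em absorbances at excitation and emission wavelengths
#'   (>= 0).
#' @return Corrected intensity.
#' @export
ife_correct <- function(intensity, abs_ex, abs_em) {
  if (any(abs_ex < 0) || any(abs_em < 0)) {
    stop("negative absorbance supplied to inner-filter correction")
  }
  intensity * 10^((abs_ex + abs_em) / 2)
}

#' FRET efficiency from intensities
#'
#' E = 1 - I_DA / I_D, the fractional quenching of the donor emission by the
#' acceptor.  A value above unity for `i_da` (enhancement rather than
#' quenching) yields a negative efficiency, which is returned with a
#' warning rather than silently clipped.
#'
#' @param i_da donor intensity in the presence of acceptor (vectorized).
#' @param i_d donor-only intensity (> 0).
#' @return Efficiency (can be negative for enhancement).
#' @export
efficiency_from_intensities <- function(i_da, i_d) {
  if (i_d <= 0) stop("donor-only intensity must be positive")
  e <- 1 - i_da / i_d
  if (any(e < 0)) {
    warning("negative efficiency: intensity exceeds the donor-only reference ",
            "(enhancement, not quenching)")
  }
  e
}

#' Hill binding fit of a quenching titration
#'
#' Ordinary least-squares line of log10((I_D - I_DA)/I_DA) against
#' log10(\[L\]) after inner-filter correction: the intercept is log10(K_b) and
#' the slope the Hill coefficient n, with K_d = 1/K_b.  Concentrations are
#' fitted in micromolar, so K_b is in 1/uM^n and K_d comes out directly in
#' micromolar (for n != 1 the numerical value of 1/K_b depends on the
#' concentration unit; the micromolar convention keeps K_d on the scale of
#' the titrated concentrations).
#'
#' Points where the corrected I_DA is not below I_D carry no quenching
#' signal and are excluded with a warning; at least two usable points are
#' required.
#'
#' @param series a [titration_series()].
#' @param apply_ife apply the inner-filter correction before fitting
#'   (default TRUE).
#' @return An object of class `binding_fit`: `log_kb`, `n_hill`, `kd_uM`,
#'   `r_squared`, `per_conc` (concentration, corrected intensity, raw
#'   efficiency, usable flag), `series`.
#' @export
hill_fit <- function(series, apply_ife = TRUE) {
  stopifnot(inherits(series, "titration_series"))
  i_cor <- if (apply_ife) {
    ife_correct(series$intensity, series$abs_ex, series$abs_em)
  } else series$intensity
  usable <- i_cor < series$i_d
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with I_DA >= I_D excluded from the fit")
  }
  if (sum(usable) < 2) {
    stop("fewer than 2 usable concentrations (corrected I_DA < I_D); cannot fit")
  }
  x <- log10(series$conc_uM[usable])
  y <- log10((series$i_d - i_cor[usable]) / i_cor[usable])
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  e_raw <- efficiency_from_intensities(i_cor, series$i_d)
  structure(list(log_kb = unname(co[1]), n_hill = unname(co[2]),
                 kd_uM = 10^(-unname(co[1])),
                 r_squared = r2,
                 per_conc = data.frame(conc_uM = series$conc_uM,
                                       intensity_corrected = i_cor,
                                       e_raw = e_raw, usable = usable),
                 series = series),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Binding fit (%s): Kd = %.4g uM, n = %.3f, R^2 = %.4f",
              x$series$ligand_id, x$kd_uM, x$n_hill, x$r_squared))
  if (!is.null(x$e_final)) cat(sprintf(", E_final = %.4f", x$e_final))
  cat("\n")
  invisible(x)
}

#' Fraction-bound-corrected FRET efficiencies
#'
#' Divides each raw per-concentration efficiency by the fraction of
#' ligand-bound protein f(\[L\]) = \[L\]^n / (K_d^n + \[L\]^n) (Hill isotherm;
#' `n = 1` gives the Langmuir form), so that partial saturation does not
#' dilute the efficiency of the bound complex.  Values are clipped to
#' \[0, 1\] with the number of clipping events reported (over-correction at
#' low f must stay visible), concentrations with f below `min_fraction` are
#' excluded as unstable, and the final efficiency is the mean over the
#' remaining concentrations.
#'
#' @param series a [titration_series()] (only used via `fit` if omitted).
#' @param fit a [hill_fit()] result; its `kd_uM` and `n_hill` are the
#'   defaults for the isotherm parameters.
#' @param kd_uM,n_hill binding parameters for the fraction-bound isotherm;
#'   override the fitted values, e.g. to use independently known constants.
#' @param min_fraction smallest usable fraction bound (default 1e-3).
#' @return The completed `binding_fit`, with `per_conc` gaining columns
#'   `fraction_bound`, `e_corrected`, `clipped`, plus fields `e_final` and
#'   `n_clipped`.
#' @export
corrected_efficiency <- function(series = fit$series, fit,
                                 kd_uM = fit$kd_uM, n_hill = fit$n_hill,
                                 min_fraction = 1e-3) {
  stopifnot(inherits(fit, "binding_fit"), kd_uM > 0)
  pc <- fit$per_conc
  f <- series$conc_uM^n_hill / (kd_uM^n_hill + series$conc_uM^n_hill)
  use <- pc$usable & f >= min_fraction
  if (!any(use)) stop("no concentration with usable signal and fraction bound >= ",
                      min_fraction)
  e_cor <- ifelse(use, pc$e_raw / f, NA_real_)
  clipped <- !is.na(e_cor) & (e_cor < 0 | e_cor > 1)
  if (any(clipped)) {
    message(sum(clipped), " corrected efficiency value(s) clipped to [0, 1]")
  }
  e_clip <- pmin(pmax(e_cor, 0), 1)
  out <- fit
  out$per_conc$fraction_bound <- f
  out$per_conc$e_corrected <- e_clip
  out$per_conc$clipped <- clipped
  out$kd_uM_used <- kd_uM
  out$n_hill_used <- n_hill
  out$n_clipped <- sum(clipped)
  out$e_final <- mean(e_clip[use])
  out
}

#' Rank simulated binding sites against an experimental efficiency
#'
#' Computes the absolute deviation |E_exp - E_site| for each candidate
#' binding site's simulated mean efficiency, ranks sites by deviation
#' (ties broken by site name), and flags sites whose deviation exceeds the
#' rule-out threshold.  Deviations beyond roughly 0.2-0.3 are large enough
#' to discard a site as the major binding model; the default threshold 0.25
#' sits mid-band.
#'
#' @param e_exp experimental efficiency (single value in \[0, 1\]).
#' @param site_means named numeric vector of simulated per-site mean
#'   efficiencies.
#' @param threshold rule-out deviation threshold (default 0.25).
#' @return Data frame sorted by deviation: `site`, `e_sim`, `deviation`,
#'   `ruled_out`.
#' @export
compare_to_simulation <- function(e_exp, site_means, threshold = 0.25) {
  if (length(e_exp) != 1 || !is.finite(e_exp)) {
    stop("e_exp must be a single finite efficiency")
  }
  if (length(site_means) < 1) stop("at least one site mean is required")
  if (is.null(names(site_means))) {
    names(site_means) <- paste0("site", seq_along(site_means))
  }
  dev <- abs(e_exp - site_means)
  out <- data.frame(site = names(site_means), e_sim = unname(site_means),
                    deviation = unname(dev),
                    ruled_out = unname(dev > threshold),
                    stringsAsFactors = FALSE)
  out <- out[order(out$deviation, out$site), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "e_exp") <- e_exp
  attr(out, "threshold") <- threshold
  out
}
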