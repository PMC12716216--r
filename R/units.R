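# Physical constants (CODATA 2014 values, atomic-unit conversions).
# Internal convention: coordinates are stored in Angstrom and converted to
# bohr at the point where an energy or field is evaluated; charges are in
# elementary-charge units; dipoles in e*bohr; energies in Hartree.

ANG2BOHR <- 1.889726124626
BOHR2ANG <- 1 / ANG2BOHR
HARTREE2CM <- 219474.6313632

#' Unit conversion helpers
#'
#' Convert energies between Hartree (the internal unit for electronic
#' couplings) and wavenumbers, and lengths between Angstrom and bohr.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' hartree_to_cm(1)     # 219474.63...
#' angstrom_to_bohr(1)  # 1.8897...
#' @export
hartree_to_cm <- function(x) x * HARTREE2CM

#' @rdname hartree_to_cm
#' @export
cm_to_hartree <- function(x) x / HARTREE2CM

#' @rdname hartree_to_cm
#' @export
angstrom_to_bohr <- function(x) x * ANG2BOHR

#' @rdname hartree_to_cm
#' @export
bohr_to_angstrom <- function(x) x * BOHR2ANG
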