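#' Unit conversions
#'
#' Conversions between the unit systems met at the package boundary:
#' hartree/eV for energies, nm/eV for photons, atomic units/fs for times
#' and bohr/angstrom for lengths.  Internally the package stores times in
#' fs and energies in eV; atomic units are accepted at the boundary only.
#' All factors come from [hbi_constants] (CODATA 2018) and every
#' conversion is exactly invertible on its domain.
#'
#' @param e Energy value(s).
#' @param lambda Wavelength(s) in nm, strictly positive.
#' @param t Time value(s).
#' @param x Length value(s).
#' @return Numeric vector of converted values.
#' @examples
#' hartree_to_ev(0.216)        # ~5.88 eV
#' nm_to_ev(325)               # ~3.8 eV
#' au_time_to_fs(20)           # ~0.484 fs
#' @name units
NULL

#' @rdname units
#' @export
hartree_to_ev <- function(e) e * hbi_constants$hartree_ev

#' @rdname units
#' @export
ev_to_hartree <- function(e) e / hbi_constants$hartree_ev

#' @rdname units
#' @export
nm_to_ev <- function(lambda) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("nm_to_ev: wavelength must be finite and > 0", call. = FALSE)
  hbi_constants$hc_ev_nm / lambda
}

#' @rdname units
#' @export
ev_to_nm <- function(e) {
  if (any(!is.finite(e)) || any(e <= 0))
    stop("ev_to_nm: photon energy must be finite and > 0", call. = FALSE)
  hbi_constants$hc_ev_nm / e
}

#' @rdname units
#' @export
au_time_to_fs <- function(t) t * hbi_constants$au_time_fs

#' @rdname units
#' @export
fs_to_au_time <- function(t) t / hbi_constants$au_time_fs

#' @rdname units
#' @export
bohr_to_angstrom <- function(x) x * hbi_constants$bohr_angstrom

#' @rdname units
#' @export
angstrom_to_bohr <- function(x) x / hbi_constants$bohr_angstrom
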