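#' Physical constants used throughout the package
#'
#' A single table of CODATA 2018 values; every conversion in the package
#' draws on this table so that no constant is ever inlined twice.
#'
#' @format A named list:
#' \describe{
#'   \item{hartree_ev}{One hartree in electronvolt.}
#'   \item{hc_ev_nm}{Product \eqn{hc} in eV nm (photon energy times wavelength).}
#'   \item{au_time_fs}{One atomic unit of time in femtoseconds.}
#'   \item{bohr_angstrom}{One bohr in angstrom.}
#'   \item{amu_me}{One unified atomic mass unit in electron masses.}
#' }
#' @export
#' @examples
#' hbi_constants$hartree_ev
hbi_constants <- list(
  hartree_ev    = 27.211386245988,
  hc_ev_nm      = 1239.8419843320026,
  au_time_fs    = 0.02418884254,
  bohr_angstrom = 0.529177210903,
  amu_me        = 1822.888486209
)

## Effective mass (in electron masses) of the mass-weighted branching-plane
## coordinates: one unified atomic mass unit by convention.  Recorded in
## trajectory headers.
.hbi_mass_au <- function() hbi_constants$amu_me
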