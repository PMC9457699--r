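#' Physical constants and unit conversions
#'
#' Single shared constants table used by every analyzer and every synthetic
#' generator, so that oracles and implementations cannot drift apart.
#' Internal units are CHARMM-native: length in Angstrom, time in ps, energy
#' in kcal/mol.  Diffusion output is in nm^2/ns, viscosity input in cP.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/(mol K) = 0.0019872041}
#'   \item{kB_SI}{Boltzmann constant, J/K}
#'   \item{xi_EW}{Ewald self-term constant of the cubic-lattice Yeh-Hummer
#'     correction, 2.837297 (dimensionless)}
#'   \item{cP_to_Pas}{1 cP in Pa s}
#'   \item{A_to_m}{1 Angstrom in m}
#'   \item{m2s_to_nm2ns}{1 m^2/s in nm^2/ns}
#'   \item{A2ps_to_nm2ns}{1 A^2/ps in nm^2/ns}
#' }
#' @export
ff_constants <- list(
  kB          = 0.0019872041,
  kB_SI       = 1.380649e-23,
  xi_EW       = 2.837297,
  cP_to_Pas   = 1e-3,
  A_to_m      = 1e-10,
  m2s_to_nm2ns = 1e9,
  A2ps_to_nm2ns = 1e-2 * 1e3  # A^2 -> nm^2 is 1e-2, 1/ps -> 1/ns is 1e3
)

#' Inverse temperature in (kcal/mol)^-1
#'
#' @param temperature temperature in K
#' @return beta = 1/(kB T) in mol/kcal
#' @export
beta_kcal <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (ff_constants$kB * temperature)
}
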