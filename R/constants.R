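#' Physical constants used throughout the package
#'
#' Single source of truth for unit conversions: the free-energy, entropy and
#' quasi-harmonic modules all read from this table so that thermodynamic
#' identities (e.g. \eqn{\Delta\Delta H - T\Delta\Delta S = \Delta\Delta G})
#' hold bit-for-bit across modules.
#'
#' Energies are kcal/mol, masses amu, lengths Angstrom, temperatures Kelvin.
#'
#' @format A named list:
#' \describe{
#'   \item{kB}{Boltzmann constant, kcal/mol/K (1.987204e-3).}
#'   \item{hbar}{Reduced Planck constant, J s.}
#'   \item{avogadro}{Avogadro's number, 1/mol.}
#'   \item{joule_per_kcal}{J per kcal (4184).}
#'   \item{kg_per_amu}{kg per atomic mass unit.}
#'   \item{m2_per_A2}{m^2 per Angstrom^2 (1e-20).}
#' }
#' @export
PHYS_CONST <- list(
  kB            = 1.987204e-3,
  hbar          = 1.054571817e-34,
  avogadro      = 6.02214076e23,
  joule_per_kcal = 4184,
  kg_per_amu    = 1.66053906660e-27,
  m2_per_A2     = 1e-20
)

# k_B * T in Joule per molecule
.kBT_joule <- function(temperature) {
  PHYS_CONST$kB * temperature * PHYS_CONST$joule_per_kcal / PHYS_CONST$avogadro
}

# thermal energy in kcal/mol
.kBT <- function(temperature) PHYS_CONST$kB * temperature
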