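# Internal unit system: length A, time ps, mass amu, charge e, energy kJ/mol.
# 1 amu A^2/ps^2 = 0.01 kJ/mol, so `.KJ_PER_INTERNAL` converts kinetic terms.

#' Physical constants used throughout the package
#'
#' A named list of constants in the package's internal unit system
#' (angstrom, picosecond, atomic mass unit, elementary charge, kJ/mol):
#' \describe{
#'   \item{kB}{Boltzmann constant, kJ/mol/K.}
#'   \item{kB_J}{Boltzmann (gas) constant, J/mol/K.}
#'   \item{ke}{Coulomb constant, kJ/mol * A / e^2 (vacuum).}
#'   \item{h}{Planck constant, kJ/mol * ps.}
#'   \item{NA_mol}{Avogadro constant, 1/mol.}
#'   \item{amuA2ps2_to_kJmol}{Energy conversion 1 amu A^2/ps^2 -> kJ/mol.}
#'   \item{invA3_to_molL}{Number density conversion 1/A^3 -> mol/L.}
#' }
#'
#' @examples
#' ha_constants()$kB * 300   # thermal energy at 300 K, kJ/mol
#' @export
ha_constants <- function() {
  list(
    kB = 0.008314462618,
    kB_J = 8.314462618,
    ke = 1389.35457644382,
    h = 0.399031002270895,
    NA_mol = 6.02214076e23,
    amuA2ps2_to_kJmol = 0.01,
    invA3_to_molL = 1e27 / 6.02214076e23
  )
}

.kB <- 0.008314462618          # kJ/mol/K
.kB_J <- 8.314462618           # J/mol/K
.KE_COUL <- 1389.35457644382   # kJ/mol A e^-2
.H_PLANCK <- 0.399031002270895 # kJ/mol ps
.NA <- 6.02214076e23
.KJ_PER_INTERNAL <- 0.01       # amu A^2 ps^-2 -> kJ/mol
.INV_A3_TO_MOLL <- 1e27 / 6.02214076e23

# kT in internal kinetic units (amu A^2/ps^2)
.kT_internal <- function(temperature) .kB * temperature / .KJ_PER_INTERNAL
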