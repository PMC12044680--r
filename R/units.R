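# Physical constants in "real" MD units: length Angstrom, time fs,
# mass amu, energy kcal/mol, charge e, temperature K.

#' Physical constants used throughout the package
#'
#' Real-unit constants: Boltzmann constant in kcal/mol/K, the Coulomb
#' prefactor in kcal*Angstrom/(mol*e^2), Avogadro's number, and the
#' conversion between amu*(A/fs)^2 and kcal/mol.
#'
#' @format A named list with elements `kB`, `coulomb`, `avogadro`,
#'   `mvsq_to_kcal` (1 amu (A/fs)^2 in kcal/mol) and `A3_to_L`
#'   (1 cubic Angstrom in litres).
#' @export
pdms_constants <- list(
  kB           = 0.0019872041,   # kcal/mol/K
  coulomb      = 332.06371,      # kcal*A/(mol*e^2)
  avogadro     = 6.02214076e23,
  mvsq_to_kcal = 2390.0573,      # 1 amu * (A/fs)^2 in kcal/mol
  A3_to_L      = 1e-27
)

# acceleration conversion: F[kcal/mol/A] / m[amu] -> A/fs^2
.ftm2a <- 1 / pdms_constants$mvsq_to_kcal
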