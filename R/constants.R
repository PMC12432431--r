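# Physical constants (CODATA 2018) and unit conversions. Internal units are
# kcal/mol for energy, nm for length, amu (g/mol) for mass, ps for time.

.kB_kcal <- 0.0019872041      # Boltzmann constant, kcal/mol/K
.kcal2kJ <- 4.184             # 1 kcal = 4.184 kJ; 1 kJ/mol = 1 amu nm^2/ps^2
.e_C <- 1.602176634e-19       # elementary charge, C
.eps0 <- 8.8541878128e-12     # vacuum permittivity, C^2 N^-1 m^-2
.kB_J <- 1.380649e-23         # Boltzmann constant, J/K
.NA_mol <- 6.02214076e23      # Avogadro constant, 1/mol

# Coulomb energy prefactor e^2/(4 pi eps0) for unit charges at 1 nm
# separation, in kcal/mol: 138.935458 kJ/mol / 4.184.
.coulomb_kcal_nm <- 138.935458 / .kcal2kJ

#' Boltzmann constant in model energy units
#'
#' @return Boltzmann constant in kcal/mol/K.
#' @export
boltzmannConstant <- function() .kB_kcal

.validTemperatureRange <- c(273, 373)

.checkTemperature <- function(T, range = .validTemperatureRange) {
  if (!is.numeric(T) || any(!is.finite(T)))
    stop("temperature must be finite numeric", call. = FALSE)
  bad <- T < range[1] | T > range[2]
  if (any(bad))
    stop(sprintf(
      "temperature %g K outside the liquid-water validity range [%g, %g] K",
      T[which(bad)[1]], range[1], range[2]), call. = FALSE)
  invisible(T)
}

# canonical amino acids, one-letter codes
.aaCodes <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# residues whose pair energies acquire temperature dependence
.hydrophobicSet <- c("A", "V", "I", "L", "M")
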