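# Physical constants (SI, CODATA 2018) and unit conversions. Energies are
# handled internally in units of kT at the simulation temperature; tables
# report kJ/mol, kcal/mol or pK units (1 pK unit = ln(10) kT).

.constants <- list(
  kB   = 1.380649e-23,     # J/K
  Nav  = 6.02214076e23,    # 1/mol
  e    = 1.602176634e-19,  # C
  eps0 = 8.8541878128e-12  # F/m
)

#' Thermal energy conversions
#'
#' `kT_kJmol()` and `kT_kcalmol()` return the thermal energy kT expressed in
#' kJ/mol and kcal/mol respectively, computed from physical constants
#' (1 kcal = 4.184 kJ exactly).
#'
#' @param temperature Absolute temperature in K (default 310 K, the
#'   physiological temperature used throughout the package).
#' @return A single number, kT in the requested unit.
#' @examples
#' kT_kcalmol(310)  # ~0.616 kcal/mol
#' @export
kT_kJmol <- function(temperature = 310) {
  .constants$kB * .constants$Nav * temperature / 1000
}

#' @rdname kT_kJmol
#' @export
kT_kcalmol <- function(temperature = 310) kT_kJmol(temperature) / 4.184

#' Bjerrum length
#'
#' Distance at which two unit charges interact with energy kT in a uniform
#' dielectric.
#'
#' @param dielectric Relative permittivity of the medium (default 80, bulk
#'   water).
#' @param temperature Temperature in K.
#' @return Length in nm.
#' @export
bjerrum_length <- function(dielectric = 80, temperature = 310) {
  with(.constants, e^2 / (4 * pi * eps0 * dielectric * kB * temperature)) * 1e9
}

#' Debye screening length
#'
#' @param ionic_strength Ionic strength in mol/L (default 0.1 M).
#' @inheritParams bjerrum_length
#' @return Length in nm (`Inf` at zero ionic strength).
#' @export
debye_length <- function(ionic_strength = 0.1, dielectric = 80,
                         temperature = 310) {
  if (ionic_strength <= 0) return(Inf)
  with(.constants,
       sqrt(eps0 * dielectric * kB * temperature /
              (2 * Nav * e^2 * ionic_strength * 1e3))) * 1e9
}

#' Screened-Coulomb pair energy
#'
#' Debye-Hueckel interaction energy between two point charges in a uniform
#' dielectric with salt screening. This is the simplified surrogate used in
#' place of a grid Poisson-Boltzmann solve for site-site couplings on model
#' systems.
#'
#' @param r Separation in nm (must be > 0).
#' @param qi,qj Charges in elementary-charge units.
#' @inheritParams debye_length
#' @return Energy in kT. Divide by `log(10)` for pK units.
#' @export
screened_coulomb_kT <- function(r, qi = 1, qj = 1, ionic_strength = 0.1,
                                dielectric = 80, temperature = 310) {
  if (any(r <= 0)) stop("charge separation must be positive", call. = FALSE)
  lb <- bjerrum_length(dielectric, temperature)
  ld <- debye_length(ionic_strength, dielectric, temperature)
  qi * qj * lb / r * exp(-r / ld)
}
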