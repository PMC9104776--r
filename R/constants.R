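#' GROMACS-style unit system and physical constants
#'
#' The package works throughout in the GROMACS molecular-dynamics unit
#' system: length in nm, time in ps, mass in amu, energy in kJ/mol,
#' temperature in K. Velocities are therefore nm/ps and forces
#' kJ/(mol nm). The Boltzmann constant in these units is
#' `kB = 0.0083144621` kJ/(mol K).
#'
#' @format A named list with elements `length`, `time`, `mass`, `energy`,
#'   `temperature` (unit name strings) and `kB` (numeric, kJ/(mol K)).
#' @export
unit_system <- list(
  length      = "nm",
  time        = "ps",
  mass        = "amu",
  energy      = "kJ/mol",
  temperature = "K",
  kB          = 0.0083144621
)

#' Boltzmann constant in kJ/(mol K)
#' @export
kB <- unit_system$kB

#' Thermal energy kB*T
#'
#' @param T temperature in K; must be positive.
#' @return `kB * T` in kJ/mol.
#' @examples
#' thermal_energy(330)  # ~2.744 kJ/mol
#' @export
thermal_energy <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || !is.finite(T) || T <= 0)
    stop("temperature must be a single positive finite number (K)")
  kB * T
}

#' Inverse thermal energy beta = 1/(kB*T)
#'
#' @param T temperature in K; must be positive.
#' @return `1/(kB*T)` in mol/kJ.
#' @export
thermal_beta <- function(T) 1 / thermal_energy(T)
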