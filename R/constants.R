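#' Physical constants and the internal unit system
#'
#' All simulation code works in an internal unit system of nanometres,
#' picoseconds and elementary charges; configuration files accept SI units
#' (diffusion coefficients in m^2/s, observed rate constants in 1/M/s) and
#' are converted once at the configuration boundary.  This avoids the
#' catastrophic exponent ranges that SI units would put into erfc arguments.
#'
#' @name units
NULL

# CODATA 2018 exact/recommended values
.const <- list(
  e_C        = 1.602176634e-19,   # elementary charge, C
  eps0_F_m   = 8.8541878128e-12,  # vacuum permittivity, F/m
  kB_J_K     = 1.380649e-23,      # Boltzmann constant, J/K
  avogadro   = 6.02214076e23      # 1/mol
)

#' Convert a diffusion coefficient from m^2/s to nm^2/ps
#' @param D_m2_s diffusion coefficient in m^2/s
#' @return diffusion coefficient in nm^2/ps
#' @export
diffusion_to_internal <- function(D_m2_s) D_m2_s * 1e6

#' Convert an observed rate constant from 1/M/s to nm^3/ps
#'
#' A bimolecular rate constant k (1/M/s) equals k * 1e24/N_A nm^3 per
#' molecule per second, i.e. k * 1e12/N_A nm^3/ps.
#'
#' @param k_M_s rate constant in 1/M/s
#' @return rate constant in nm^3/ps (per molecule pair)
#' @export
kobs_to_internal <- function(k_M_s) k_M_s * 1e12 / .const$avogadro

#' Convert a rate constant from nm^3/ps back to 1/M/s
#' @param k_nm3_ps rate constant in nm^3/ps
#' @return rate constant in 1/M/s
#' @export
kobs_from_internal <- function(k_nm3_ps) k_nm3_ps * .const$avogadro / 1e12

#' Onsager radius
#'
#' Distance at which the Coulomb energy of two unit charges equals the
#' thermal energy: rc = e^2 / (4 pi eps0 epsr kB T).  In liquid water at
#' 25 degrees C (epsr = 78.4) this evaluates to 0.71 nm, the value used for
#' all charged-pair effective-distance corrections.
#'
#' @param temperature temperature in kelvin
#' @param relative_permittivity relative permittivity of the medium
#' @return Onsager radius in nm (unsigned magnitude)
#' @examples
#' onsager_radius()  # 0.71 nm in water at 25 C
#' @export
onsager_radius <- function(temperature = 298.15, relative_permittivity = 78.4) {
  stopifnot(temperature > 0, relative_permittivity > 1)
  rc_m <- .const$e_C^2 /
    (4 * pi * .const$eps0_F_m * relative_permittivity *
       .const$kB_J_K * temperature)
  rc_m * 1e9
}

#' Physical constants bundle used by a simulation
#'
#' @param temperature kelvin
#' @param relative_permittivity dimensionless
#' @param encounter_separation Rs, the unsuccessful-encounter separation used
#'   by the contact-reaction probability, in nm (0.3 nm default)
#' @return a list with `onsager_radius` (nm), `encounter_separation` (nm),
#'   `temperature` (K) and `relative_permittivity`
#' @export
physical_constants <- function(temperature = 298.15,
                               relative_permittivity = 78.4,
                               encounter_separation = 0.3) {
  stopifnot(encounter_separation > 0)
  list(
    onsager_radius = onsager_radius(temperature, relative_permittivity),
    encounter_separation = encounter_separation,
    temperature = temperature,
    relative_permittivity = relative_permittivity
  )
}
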