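# Compton scattering physics: kinematics, Klein-Nishina cross-section and
# scatter-angle sampling. Energies in keV, cross-sections in cm^2 per
# electron.

ELECTRON_REST_KEV <- 511.0
R_ELECTRON_CM <- 2.8179403262e-13
THOMSON_CM2 <- 8 * pi / 3 * R_ELECTRON_CM^2

#' Compton-scattered photon energy
#'
#' `E' = E / (1 + (E/511) (1 - cos theta))`: energy of a photon of energy
#' `E` keV after scattering through `theta` radians off a free electron.
#'
#' @param energy_kev Incident photon energy, keV (vectorized).
#' @param angle_rad Scattering angle, radians (vectorized).
#' @return Scattered energy, keV.
#' @examples
#' compton_energy(511, pi / 2)  # 255.5 keV
#' compton_energy(511, pi)      # 170.33 keV backscatter
#' @export
compton_energy <- function(energy_kev, angle_rad) {
  stopifnot(all(energy_kev > 0))
  energy_kev / (1 + (energy_kev / ELECTRON_REST_KEV) * (1 - cos(angle_rad)))
}

#' Klein-Nishina total cross-section per electron
#'
#' Closed-form total Compton cross-section at reduced energy
#' `alpha = E / 511`; tends to the Thomson cross-section
#' (6.652e-25 cm^2) as E tends to 0 and decreases monotonically in E.
#'
#' @param energy_kev Photon energy, keV (vectorized).
#' @return Cross-section in cm^2 per electron.
#' @export
kn_total_cross_section <- function(energy_kev) {
  stopifnot(all(energy_kev > 0))
  a <- energy_kev / ELECTRON_REST_KEV
  2 * pi * R_ELECTRON_CM^2 * (
    (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log1p(2 * a) / a) +
      log1p(2 * a) / (2 * a) -
      (1 + 3 * a) / (1 + 2 * a)^2
  )
}

#' Klein-Nishina differential cross-section in cos(theta)
#'
#' `d sigma / d cos(theta)` (azimuth integrated), used by the sampling
#' tests as the analytic reference density.
#'
#' @param energy_kev Photon energy, keV.
#' @param cos_theta Cosine of the scattering angle (vectorized).
#' @return Differential cross-section, cm^2 per unit cos(theta).
#' @export
kn_differential <- function(energy_kev, cos_theta) {
  a <- energy_kev / ELECTRON_REST_KEV
  ratio <- 1 / (1 + a * (1 - cos_theta))   # E'/E
  pi * R_ELECTRON_CM^2 * ratio^2 * (ratio + 1 / ratio - (1 - cos_theta^2))
}

#' Sample Compton scattering angles from the Klein-Nishina distribution
#'
#' Kahn's composition-rejection method: exact sampling of the scattering
#' angle off a free electron at the given photon energy, with no
#' tabulation. The azimuth (not returned) is uniform by symmetry.
#'
#' @param energy_kev Photon energy, keV (scalar or vector recycled to `n`).
#' @param n Number of samples (default `length(energy_kev)`).
#' @return Scattering angles in radians, length `n`.
#' @export
sample_kn_angle <- function(energy_kev, n = length(energy_kev)) {
  stopifnot(all(energy_kev > 0))
  a <- rep_len(energy_kev / ELECTRON_REST_KEV, n)
  cost <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    ai <- a[todo]
    m <- length(todo)
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    branch1 <- u1 <= (1 + 2 * ai) / (9 + 2 * ai)
    x <- ifelse(branch1, 1 + 2 * ai * u2, (1 + 2 * ai) / (1 + 2 * ai * u2))
    ct <- 1 - (x - 1) / ai
    acc <- ifelse(branch1,
                  u3 <= 4 * (1 / x - 1 / x^2),
                  u3 <= 0.5 * (ct^2 + 1 / x))
    cost[todo[acc]] <- ct[acc]
    todo <- todo[!acc]
  }
  acos(pmin(pmax(cost, -1), 1))
}

#' Homogeneous Compton-scattering material
#'
#' Electron density from mass density and the electrons-per-mass ratio
#' Z/A; the Compton linear attenuation coefficient is
#' `mu(E) = electron_density * sigma_KN(E)`.
#'
#' @param density Mass density, g/cm^3.
#' @param z_over_a Electrons per atomic mass unit (8/14 for CH2
#'   polyethylene).
#' @return An object of class `material_model` with fields `density` and
#'   `electron_density` (electrons/cm^3).
#' @export
material_model <- function(density, z_over_a) {
  stopifnot(density >= 0, z_over_a > 0)
  structure(list(
    density = density,
    electron_density = density * 6.02214076e23 * z_over_a
  ), class = "material_model")
}

#' High-density polyethylene preset (0.96 g/cm^3, CH2)
#' @return A `material_model`.
#' @export
material_polyethylene <- function() material_model(0.96, 8 / 14)

#' Compton linear attenuation coefficient
#'
#' @param material A `material_model`.
#' @param energy_kev Photon energy, keV (vectorized).
#' @return mu in 1/cm.
#' @export
mu_compton <- function(material, energy_kev) {
  material$electron_density * kn_total_cross_section(energy_kev)
}
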