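#' Cylindrical crystal-ring PET scanner specification
#'
#' The detector is modeled as a continuous cylinder at the inner ring
#' radius, discretized into `crystals_per_ring` equal angular sectors and
#' `n_rings` axial rings of pitch `axial_fov / n_rings`. There are no
#' inter-crystal gaps and no scintillator distinction: one Gaussian energy
#' resolution model (FWHM proportional to deposited energy) covers all
#' crystals, which is adequate for scatter-fraction and count-rate trends.
#'
#' @param name Scanner label.
#' @param ring_inner_diameter_mm Inner diameter of the crystal ring, mm.
#' @param crystals_per_ring,n_rings Detector granularity.
#' @param axial_fov_mm Axial field of view, mm.
#' @param crystal_depth_mm Crystal depth, mm (used by the optional
#'   interaction-probability detection model).
#' @param energy_resolution FWHM fraction of the Gaussian energy blur at
#'   511 keV (0.25 = 25 percent).
#' @param let_kev,uet_kev Lower / upper energy thresholds, keV.
#' @param coincidence_window_ns Coincidence timing window, ns.
#' @param timing_resolution_ns FWHM of the per-single Gaussian timing blur,
#'   ns (0 disables).
#' @param crystal_mu_511_cm Linear attenuation coefficient of the
#'   scintillator at 511 keV, 1/cm; only used when the interaction-
#'   probability detection model is enabled (see [detect_photons()]).
#' @return An object of class `scanner_spec`.
#' @export
scanner_spec <- function(name,
                         ring_inner_diameter_mm,
                         crystals_per_ring,
                         n_rings,
                         axial_fov_mm,
                         crystal_depth_mm,
                         energy_resolution = 0.25,
                         let_kev = 250,
                         uet_kev = 750,
                         coincidence_window_ns = 20,
                         timing_resolution_ns = 0,
                         crystal_mu_511_cm = 0.95) {
  stopifnot(ring_inner_diameter_mm > 0, crystals_per_ring > 1, n_rings >= 1,
            axial_fov_mm > 0, energy_resolution >= 0,
            let_kev >= 0, uet_kev > let_kev, coincidence_window_ns > 0)
  pitch <- axial_fov_mm / n_rings
  structure(list(
    name = name,
    ring_inner_diameter_mm = ring_inner_diameter_mm,
    crystals_per_ring = crystals_per_ring,
    n_rings = n_rings,
    crystal_axial_pitch_mm = pitch,
    crystal_depth_mm = crystal_depth_mm,
    axial_fov_mm = axial_fov_mm,
    energy_resolution = energy_resolution,
    let_kev = let_kev,
    uet_kev = uet_kev,
    coincidence_window_ns = coincidence_window_ns,
    timing_resolution_ns = timing_resolution_ns,
    crystal_mu_511_cm = crystal_mu_511_cm
  ), class = "scanner_spec")
}

#' @export
print.scanner_spec <- function(x, ...) {
  cat(sprintf(
    "<scanner_spec> %s: %d rings x %d crystals, ring d = %g mm, axial FOV = %g mm,\n  window %g-%g keV, dE/E = %g, coincidence window %g ns\n",
    x$name, x$n_rings, x$crystals_per_ring, x$ring_inner_diameter_mm,
    x$axial_fov_mm, x$let_kev, x$uet_kev, x$energy_resolution,
    x$coincidence_window_ns))
  invisible(x)
}

#' BGO block scanner preset (X-PET class)
#'
#' 48 rings x 240 crystals (11,520 total), 165 mm inner ring diameter,
#' 116 mm axial FOV, 250-750 keV energy window, 25 percent energy
#' resolution. The coincidence window is not part of the published
#' specification; the 12 ns default (and the 3 ns timing blur) are
#' documented assumptions, immaterial in the low-activity regime.
#'
#' @return A `scanner_spec`.
#' @export
scanner_xpet <- function() {
  scanner_spec("X-PET",
               ring_inner_diameter_mm = 165,
               crystals_per_ring = 240,
               n_rings = 48,
               axial_fov_mm = 116,
               crystal_depth_mm = 9.4,
               energy_resolution = 0.25,
               let_kev = 250, uet_kev = 750,
               coincidence_window_ns = 12,
               timing_resolution_ns = 3,
               crystal_mu_511_cm = 0.95)   # BGO
}

#' LYSO/LGSO phoswich scanner preset (LabPET-8 class)
#'
#' 32 rings x 192 crystals (6,144 total), 162 mm inner ring diameter,
#' 75 mm axial FOV, 250-650 keV energy window, 20 ns coincidence window,
#' 9 ns timing resolution, 25 percent energy resolution. The phoswich
#' LYSO/LGSO distinction is not modeled; a single window and energy
#' response stand for both members.
#'
#' @return A `scanner_spec`.
#' @export
scanner_labpet8 <- function() {
  scanner_spec("LabPET-8",
               ring_inner_diameter_mm = 162,
               crystals_per_ring = 192,
               n_rings = 32,
               axial_fov_mm = 75,
               crystal_depth_mm = 14,
               energy_resolution = 0.25,
               let_kev = 250, uet_kev = 650,
               coincidence_window_ns = 20,
               timing_resolution_ns = 9,
               crystal_mu_511_cm = 0.87)   # LYSO
}

#' Map a spatial hit on the detector cylinder to crystal indices
#'
#' The azimuth index is `floor(phi / (2 pi / crystals_per_ring))` with
#' `phi` in `[0, 2 pi)` measured from +x; the ring index comes from z
#' within the axial FOV (ring 0 at the -z edge). Positions whose axial
#' coordinate falls outside the FOV are misses (`NA` indices). Zero-based
#' indices.
#'
#' @param scanner A `scanner_spec`.
#' @param position Length-3 vector or n x 3 matrix, mm, scanner frame
#'   (FOV centered at z = 0).
#' @param radial_tol Allowed deviation of the hit radius from the inner
#'   ring radius, mm.
#' @return A list with integer vectors `ring` and `azimuth` (`NA` = miss).
#' @export
crystal_of_hit <- function(scanner, position, radial_tol = 1) {
  if (is.null(dim(position))) position <- matrix(position, ncol = 3)
  R <- scanner$ring_inner_diameter_mm / 2
  r <- sqrt(position[, 1]^2 + position[, 2]^2)
  if (any(abs(r - R) > radial_tol))
    stop("hit radius does not lie on the detector cylinder", call. = FALSE)
  phi <- atan2(position[, 2], position[, 1]) %% (2 * pi)
  az <- pmin(floor(phi / (2 * pi / scanner$crystals_per_ring)),
             scanner$crystals_per_ring - 1)
  zrel <- position[, 3] + scanner$axial_fov_mm / 2
  ring <- floor(zrel / scanner$crystal_axial_pitch_mm)
  miss <- ring < 0 | ring >= scanner$n_rings
  ring[miss] <- NA_integer_
  az[miss] <- NA_integer_
  list(ring = as.integer(ring), azimuth = as.integer(az))
}

#' Center of a crystal on the inner ring surface
#'
#' Inverse of [crystal_of_hit()] up to quantization: the point at the
#' crystal's angular and axial center on the inner-ring radius.
#'
#' @param scanner A `scanner_spec`.
#' @param ring,azimuth Zero-based indices (vectors allowed).
#' @return n x 3 matrix of positions, mm, scanner frame.
#' @export
crystal_center <- function(scanner, ring, azimuth) {
  if (any(ring < 0 | ring >= scanner$n_rings) ||
      any(azimuth < 0 | azimuth >= scanner$crystals_per_ring))
    stop("crystal index out of range", call. = FALSE)
  R <- scanner$ring_inner_diameter_mm / 2
  dphi <- 2 * pi / scanner$crystals_per_ring
  phi <- (azimuth + 0.5) * dphi
  z <- -scanner$axial_fov_mm / 2 + (ring + 0.5) * scanner$crystal_axial_pitch_mm
  cbind(x = R * cos(phi), y = R * sin(phi), z = z)
}
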