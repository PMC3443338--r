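#' Line source inside the phantom
#'
#' An ideal (infinitely thin) positron-emitting line parallel to the
#' phantom axis at a given radial offset. The active axial range is
#' `[z_start, z_end]` in the phantom frame; use [clip_line_to_phantom()]
#' to restrict a requested range to where the line actually lies inside
#' the material.
#'
#' @param radial_offset_mm Radial offset from the axis, mm.
#' @param z_start,z_end Active axial range, cm (phantom frame).
#' @param activity_bq Source activity, Bq; the default 1e5 Bq realizes the
#'   low-activity regime in which randoms and dead time are negligible.
#' @param isotope Label only (back-to-back 511 keV pairs are emitted
#'   regardless; positron range and acollinearity are not modeled).
#' @return An object of class `line_source`.
#' @export
line_source <- function(radial_offset_mm, z_start, z_end,
                        activity_bq = 1e5, isotope = "back-to-back") {
  stopifnot(radial_offset_mm >= 0, z_end > z_start, activity_bq > 0)
  structure(list(radial_offset_mm = radial_offset_mm,
                 z_start = z_start, z_end = z_end,
                 activity_bq = activity_bq, isotope = isotope),
            class = "line_source")
}

#' Clip a line-source axial range to the phantom interior
#'
#' Restricts `[z_start, z_end]` to the axial range where the phantom's
#' local radius exceeds the source offset by `margin_mm`, i.e. where a
#' source channel can physically exist. Returns `NULL` when no part of the
#' range fits.
#'
#' @param phantom A `phantom_spec`.
#' @param radial_offset_mm Source offset, mm.
#' @param z_start,z_end Requested range, cm.
#' @param margin_mm Required clearance between line and surface, mm.
#' @return c(z_start, z_end) in cm, or `NULL` if infeasible.
#' @export
clip_line_to_phantom <- function(phantom, radial_offset_mm, z_start, z_end,
                                 margin_mm = 0.5) {
  need_cm <- (radial_offset_mm + margin_mm) / 10
  r0 <- phantom$min_diameter / 2
  if (need_cm <= r0) {
    zmin <- 0
  } else if (phantom$theta_deg <= 0) {
    return(NULL)
  } else {
    zmin <- (need_cm - r0) / tan_theta(phantom)
  }
  lo <- max(z_start, zmin)
  if (lo >= z_end - 1e-9) return(NULL)
  c(lo, z_end)
}

#' Emit back-to-back annihilation photon pairs
#'
#' Emission points uniform on the active line; the first photon direction
#' isotropic on the sphere, the second exactly antiparallel; both photons
#' at 511 keV with zero scatters. Emission times follow a Poisson process
#' at the source activity, giving each annihilation a unique id and time.
#'
#' @param source A `line_source`.
#' @param n_pairs Number of annihilations to emit.
#' @return A list with `events` (data.table: `id`, `time_ns`, `x`, `y`,
#'   `z`) and `photons` (data.table of 2 * n_pairs rows: `id`, `x`, `y`,
#'   `z` cm, `dx`, `dy`, `dz`, `energy_kev`, `n_scatters`, `alive`).
#' @export
emit_pairs <- function(source, n_pairs) {
  stopifnot(n_pairs >= 1)
  z <- stats::runif(n_pairs, source$z_start, source$z_end)
  x <- rep(source$radial_offset_mm / 10, n_pairs)  # line along +x offset
  y <- rep(0, n_pairs)
  t_ns <- cumsum(stats::rexp(n_pairs, source$activity_bq)) * 1e9
  # isotropic directions
  ct <- stats::runif(n_pairs, -1, 1)
  st <- sqrt(1 - ct^2)
  ph <- stats::runif(n_pairs, 0, 2 * pi)
  dx <- st * cos(ph); dy <- st * sin(ph); dz <- ct
  events <- data.table::data.table(id = seq_len(n_pairs), time_ns = t_ns,
                                   x = x, y = y, z = z)
  photons <- data.table::data.table(
    id = rep(seq_len(n_pairs), 2),
    x = rep(x, 2), y = rep(y, 2), z = rep(z, 2),
    dx = c(dx, -dx), dy = c(dy, -dy), dz = c(dz, -dz),
    energy_kev = 511, n_scatters = 0L, alive = TRUE
  )
  list(events = events, photons = photons)
}

# Rotate unit vectors (dx,dy,dz) by polar angle theta about themselves with
# uniform azimuth: returns the scattered directions.
.rotate_directions <- function(dx, dy, dz, theta) {
  n <- length(dx)
  phi <- stats::runif(n, 0, 2 * pi)
  # orthonormal frame (u, v) perpendicular to d, stable for all d
  swap <- abs(dz) > 0.999
  ux <- ifelse(swap, 1, -dy)
  uy <- ifelse(swap, 0, dx)
  uz <- rep(0, n)
  un <- sqrt(ux^2 + uy^2 + uz^2)
  ux <- ux / un; uy <- uy / un; uz <- uz / un
  vx <- dy * uz - dz * uy
  vy <- dz * ux - dx * uz
  vz <- dx * uy - dy * ux
  st <- sin(theta); ct <- cos(theta)
  cp <- cos(phi); sp <- sin(phi)
  nx <- ct * dx + st * (cp * ux + sp * vx)
  ny <- ct * dy + st * (cp * uy + sp * vy)
  nz <- ct * dz + st * (cp * uz + sp * vz)
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  cbind(nx / nrm, ny / nrm, nz / nrm)
}

#' Transport photons through the phantom with Compton scattering
#'
#' For each photon, free paths are sampled from an exponential with rate
#' `mu(E) = electron_density * sigma_KN(E)`. If the sampled path exceeds
#' the distance to the phantom surface the photon escapes with its current
#' energy and direction; otherwise it Compton-scatters (Klein-Nishina
#' angle, updated energy, scatter counter incremented). Histories falling
#' below `cutoff_kev` are killed. Photoelectric absorption and coherent
#' scattering are not modeled (negligible for polyethylene above the
#' energy windows of interest). Photons starting outside the phantom with
#' no intersection pass through unchanged.
#'
#' @param photons data.table as produced by [emit_pairs()] (modified by
#'   reference and returned).
#' @param phantom A `phantom_spec`.
#' @param material A `material_model` (mu = 0 disables interactions).
#' @param cutoff_kev Energy below which histories are terminated.
#' @param max_scatters Safety bound on scatters per photon.
#' @return The photon table with final `x`, `y`, `z` (escape point, cm),
#'   `dx`, `dy`, `dz`, `energy_kev`, `n_scatters`, and `alive` (FALSE for
#'   killed histories).
#' @export
transport_photons <- function(photons, phantom, material,
                              cutoff_kev = 50, max_scatters = 100L) {
  x <- photons$x; y <- photons$y; z <- photons$z
  dx <- photons$dx; dy <- photons$dy; dz <- photons$dz
  E <- photons$energy_kev
  ns <- photons$n_scatters
  alive <- photons$alive
  active <- which(alive)
  # photons starting outside the phantom: escape immediately (possibly
  # crossing it is not supported for emission use-cases; sources are inside)
  if (length(active)) {
    ins <- .inside_phantom(phantom, x[active], y[active], z[active])
    active <- active[ins]
  }
  iter <- 0L
  while (length(active)) {
    iter <- iter + 1L
    if (iter > max_scatters) break
    mu <- material$electron_density * kn_total_cross_section(E[active])
    s <- stats::rexp(length(active)) / mu          # Inf when mu = 0
    dexit <- .dist_to_exit(phantom, x[active], y[active], z[active],
                           dx[active], dy[active], dz[active])
    esc <- s >= dexit
    # escaping photons: advance to the surface, done
    ei <- active[esc]
    if (length(ei)) {
      de <- dexit[esc]
      x[ei] <- x[ei] + de * dx[ei]
      y[ei] <- y[ei] + de * dy[ei]
      z[ei] <- z[ei] + de * dz[ei]
    }
    # scattering photons: advance, sample angle, update energy/direction
    si <- active[!esc]
    if (length(si)) {
      ds <- s[!esc]
      x[si] <- x[si] + ds * dx[si]
      y[si] <- y[si] + ds * dy[si]
      z[si] <- z[si] + ds * dz[si]
      theta <- sample_kn_angle(E[si])
      E[si] <- compton_energy(E[si], theta)
      nd <- .rotate_directions(dx[si], dy[si], dz[si], theta)
      dx[si] <- nd[, 1]; dy[si] <- nd[, 2]; dz[si] <- nd[, 3]
      ns[si] <- ns[si] + 1L
      dead <- E[si] < cutoff_kev
      alive[si[dead]] <- FALSE
      si <- si[!dead]
    }
    active <- si
  }
  data.table::set(photons, j = "x", value = x)
  data.table::set(photons, j = "y", value = y)
  data.table::set(photons, j = "z", value = z)
  data.table::set(photons, j = "dx", value = dx)
  data.table::set(photons, j = "dy", value = dy)
  data.table::set(photons, j = "dz", value = dz)
  data.table::set(photons, j = "energy_kev", value = E)
  data.table::set(photons, j = "n_scatters", value = ns)
  data.table::set(photons, j = "alive", value = alive)
  photons
}
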