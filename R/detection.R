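#' Detect escaped photons on the crystal ring
#'
#' Each escaping photon is propagated along a straight line to the
#' detector cylinder (inner ring radius). A photon whose intersection
#' falls inside the axial FOV deposits its full energy with probability
#' `p_det` (1 by default; optionally the interaction probability
#' `1 - exp(-mu_crystal * depth / |sin of incidence|)` is approximated by
#' the normal-incidence `1 - exp(-mu_crystal * depth)`). The deposit is
#' blurred with a Gaussian of FWHM `energy_resolution * E` and the single
#' is timestamped with the annihilation time plus an optional Gaussian
#' timing blur. No energy window is applied here: windowing is a separate
#' deterministic step ([apply_energy_window()]) so that threshold sweeps
#' reuse identical blur draws.
#'
#' @param photons Transported photon table ([transport_photons()]); killed
#'   histories are ignored.
#' @param events Annihilation table from [emit_pairs()] (for times).
#' @param scanner A `scanner_spec`.
#' @param z_center Axial position (cm, phantom frame) of the scanner FOV
#'   center; the segment midpoint for an acquisition.
#' @param use_interaction_prob If TRUE, thin the hits with the crystal
#'   interaction probability `1 - exp(-mu_crystal_511 * depth)` (used for
#'   absolute sensitivity; scatter-fraction work keeps the default ideal
#'   capture, which cancels in count ratios).
#' @return data.table of singles: `id`, `ring`, `azimuth`, `energy_kev`
#'   (blurred), `time_ns`, `scattered` (ground-truth phantom-scatter
#'   flag), sorted by time.
#' @export
detect_photons <- function(photons, events, scanner, z_center,
                           use_interaction_prob = FALSE) {
  p <- photons[photons$alive & photons$energy_kev > 0, ]
  R_cm <- scanner$ring_inner_diameter_mm / 20   # mm -> cm radius
  a <- p$dx^2 + p$dy^2
  b <- 2 * (p$x * p$dx + p$y * p$dy)
  cc <- p$x^2 + p$y^2 - R_cm^2
  disc <- b^2 - 4 * a * cc
  ok <- a > 1e-12 & disc > 0
  t <- rep(NA_real_, nrow(p))
  t[ok] <- (-b[ok] + sqrt(disc[ok])) / (2 * a[ok])   # outward root (cc < 0)
  ok <- ok & t > 0
  zhit <- p$z + t * p$dz
  half <- scanner$axial_fov_mm / 20               # cm half-FOV
  ok <- ok & !is.na(zhit) & abs(zhit - z_center) <= half
  hit <- p[which(ok), ]
  th <- t[ok]
  if (nrow(hit) == 0) {
    return(data.table::data.table(
      id = integer(), ring = integer(), azimuth = integer(),
      energy_kev = numeric(), time_ns = numeric(), scattered = logical()))
  }
  if (use_interaction_prob) {
    pdet <- 1 - exp(-scanner$crystal_mu_511_cm * scanner$crystal_depth_mm / 10)
    keep <- stats::runif(nrow(hit)) < pdet
    hit <- hit[keep, ]
    th <- th[keep]
  }
  pos_mm <- cbind((hit$x + th * hit$dx) * 10,
                  (hit$y + th * hit$dy) * 10,
                  (hit$z + th * hit$dz - z_center) * 10)
  idx <- crystal_of_hit(scanner, pos_mm)
  sigma_e <- scanner$energy_resolution * hit$energy_kev / 2.3548
  eblur <- hit$energy_kev + stats::rnorm(nrow(hit), 0, sigma_e)
  tns <- events$time_ns[hit$id]
  if (scanner$timing_resolution_ns > 0)
    tns <- tns + stats::rnorm(nrow(hit), 0,
                              scanner$timing_resolution_ns / 2.3548)
  singles <- data.table::data.table(
    id = hit$id, ring = idx$ring, azimuth = idx$azimuth,
    energy_kev = eblur, time_ns = tns,
    scattered = hit$n_scatters > 0L)
  data.table::setorder(singles, time_ns)
  singles
}

#' Apply the energy acceptance window to a singles stream
#'
#' Deterministic re-windowing of already-blurred singles: accepted iff
#' `let <= energy <= uet`. Raising the lower threshold on a fixed stream
#' can only remove singles, which makes threshold sweeps variance-free
#' comparisons.
#'
#' @param singles Singles table from [detect_photons()].
#' @param let_kev,uet_kev Window bounds, keV.
#' @return The accepted subset, time order preserved.
#' @export
apply_energy_window <- function(singles, let_kev, uet_kev) {
  singles[singles$energy_kev >= let_kev & singles$energy_kev <= uet_kev, ]
}

#' Sort singles into classified coincidences
#'
#' Sliding-window pairing: a window opens at the earliest unconsumed
#' single and collects all singles within `window_ns`; exactly two give
#' one coincidence, more than two are all discarded (multiple-coincidence
#' rejection), a lone single is dropped. Each pair is classified from
#' ground truth: `true` (same annihilation, neither photon scattered in
#' the phantom), `scattered` (same annihilation, at least one scattered),
#' `random` (different annihilations).
#'
#' @param singles Time-ordered singles table (post-windowing).
#' @param window_ns Coincidence window, ns.
#' @param t_acq_s Acquisition time, s; defaults to the time span of the
#'   parent emission stream when supplied via `attr`, else the last single
#'   time.
#' @return A list of class `listmode_set`: `pairs` (data.table with the
#'   two singles' indices, crystals, energies, times, `kind`), `t_acq_s`,
#'   `window_ns`.
#' @export
sort_coincidences <- function(singles, window_ns, t_acq_s = NULL) {
  if (is.unsorted(singles$time_ns))
    stop("singles must be time-ordered", call. = FALSE)
  n <- nrow(singles)
  if (is.null(t_acq_s))
    t_acq_s <- if (n) max(singles$time_ns) * 1e-9 else 0
  a_idx <- integer(0); b_idx <- integer(0)
  if (n >= 2) {
    tt <- singles$time_ns
    # clusters separated by gaps > window; within a cluster the sliding
    # rule is applied sequentially (clusters of size 2 dominate at low
    # activity and are paired directly)
    cl <- cumsum(c(TRUE, diff(tt) > window_ns))
    sizes <- tabulate(cl)
    starts <- cumsum(c(1L, sizes[-length(sizes)]))
    two <- which(sizes == 2L)
    if (length(two)) {
      a_idx <- starts[two]
      b_idx <- starts[two] + 1L
    }
    big <- which(sizes > 2L)
    for (ci in big) {
      i <- starts[ci]; end <- starts[ci] + sizes[ci] - 1L
      while (i <= end) {
        inwin <- which(tt[i:end] - tt[i] <= window_ns) + i - 1L
        if (length(inwin) == 2L) {
          a_idx <- c(a_idx, inwin[1]); b_idx <- c(b_idx, inwin[2])
        }
        i <- max(inwin) + 1L
      }
    }
  }
  ord <- order(singles$time_ns[a_idx])
  a_idx <- a_idx[ord]; b_idx <- b_idx[ord]
  sa <- singles[a_idx, ]; sb <- singles[b_idx, ]
  kind <- ifelse(sa$id != sb$id, "random",
                 ifelse(sa$scattered | sb$scattered, "scattered", "true"))
  pairs <- data.table::data.table(
    time_ns = sa$time_ns,
    ring_a = sa$ring, az_a = sa$azimuth, energy_a = sa$energy_kev,
    ring_b = sb$ring, az_b = sb$azimuth, energy_b = sb$energy_kev,
    id_a = sa$id, id_b = sb$id,
    kind = kind)
  structure(list(pairs = pairs, t_acq_s = t_acq_s, window_ns = window_ns),
            class = "listmode_set")
}

#' @export
print.listmode_set <- function(x, ...) {
  k <- table(factor(x$pairs$kind, levels = c("true", "scattered", "random")))
  cat(sprintf(
    "<listmode_set> %d coincidences (%d true, %d scattered, %d random), T_acq = %.3g s\n",
    nrow(x$pairs), k[["true"]], k[["scattered"]], k[["random"]], x$t_acq_s))
  invisible(x)
}

#' Write / read a list-mode coincidence table as CSV
#'
#' Flat text serialization of a `listmode_set`'s pair table with a JSON
#' sidecar (`<path>.json`) carrying `t_acq_s` and `window_ns`. The
#' ground-truth `kind` column is metadata for validation and is never
#' consumed by the NEMA estimator.
#'
#' @param lm A `listmode_set`.
#' @param path CSV path.
#' @return `read_listmode` returns a `listmode_set`.
#' @export
write_listmode <- function(lm, path) {
  data.table::fwrite(lm$pairs, path)
  jsonlite::write_json(list(t_acq_s = lm$t_acq_s, window_ns = lm$window_ns),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_listmode
#' @export
read_listmode <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(pairs = data.table::fread(path),
                 t_acq_s = meta$t_acq_s, window_ns = meta$window_ns),
            class = "listmode_set")
}
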