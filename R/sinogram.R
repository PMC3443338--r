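#' Sinogram coordinates of a line of response
#'
#' For a coincidence between two crystals, the LOR is the segment joining
#' their centers projected onto the transaxial plane; `s` is the signed
#' perpendicular distance of that line from the scanner axis, and
#' `phi` in `[0, pi)` its orientation (angle of the LOR normal). Swapping
#' the crystals maps (s, phi) to the same physical line.
#'
#' @param scanner A `scanner_spec`.
#' @param ring_a,az_a,ring_b,az_b Crystal indices (vectors allowed).
#' @return A list with numeric vectors `s` (mm) and `phi` (radians in
#'   `[0, pi)`).
#' @export
lor_coordinates <- function(scanner, ring_a, az_a, ring_b, az_b) {
  if (any(ring_a == ring_b & az_a == az_b))
    stop("degenerate LOR: identical crystals", call. = FALSE)
  p1 <- crystal_center(scanner, ring_a, az_a)
  p2 <- crystal_center(scanner, ring_b, az_b)
  ex <- p2[, 1] - p1[, 1]
  ey <- p2[, 2] - p1[, 2]
  nn <- sqrt(ex^2 + ey^2)
  # LOR direction angle alpha; normal at alpha + pi/2
  phi <- (atan2(ey, ex) + pi / 2) %% pi
  # choose the normal consistent with phi in [0, pi)
  s <- p1[, 1] * cos(phi) + p1[, 2] * sin(phi)
  # guard: crystals axially stacked (nn = 0) have no transaxial LOR
  s[nn < 1e-9] <- NA_real_
  list(s = unname(s), phi = unname(phi))
}

#' Single-slice rebinning of coincidences into 2D sinograms
#'
#' Each coincidence with ring difference at most `max_ring_difference` is
#' assigned to slice `ring_a + ring_b` (0 ... 2 n_rings - 2, i.e. the ring
#' average at half-pitch resolution), and its `(s, phi)` is histogrammed
#' on the radial/angular grid. Separate cubes are kept per ground-truth
#' label along with the combined prompt cube that the NEMA estimator
#' consumes.
#'
#' Grid defaults: radial bin width half the crystal transverse pitch
#' (`pi * R / crystals_per_ring`), `n_angles = crystals_per_ring / 2`, and
#' an odd number of radial bins so a unique central bin exists.
#'
#' @param lm A `listmode_set`.
#' @param scanner A `scanner_spec`.
#' @param max_ring_difference Maximum |ring_a - ring_b| accepted
#'   (default: all).
#' @param radial_bin_mm Radial bin width, mm.
#' @param n_radial Odd number of radial bins (default: covering the ring
#'   diameter).
#' @param n_angles Number of angular bins.
#' @return An object of class `sinogram2d_set`: list with `counts` (named
#'   list of 3-d arrays `[radial, angle, slice]` for `prompt`, `true`,
#'   `scattered`, `random`), grid fields, and provenance (`t_acq_s`).
#' @export
ssrb <- function(lm, scanner,
                 max_ring_difference = scanner$n_rings - 1,
                 radial_bin_mm = pi * scanner$ring_inner_diameter_mm / 2 /
                   scanner$crystals_per_ring,
                 n_radial = NULL,
                 n_angles = scanner$crystals_per_ring / 2) {
  stopifnot(max_ring_difference <= scanner$n_rings - 1)
  R <- scanner$ring_inner_diameter_mm / 2
  if (is.null(n_radial)) n_radial <- 2L * floor(R / radial_bin_mm) + 1L
  if (n_radial %% 2 == 0) n_radial <- n_radial + 1L
  n_slices <- 2L * scanner$n_rings - 1L
  p <- lm$pairs
  cubes <- list(
    prompt = array(0L, c(n_radial, n_angles, n_slices)),
    true = array(0L, c(n_radial, n_angles, n_slices)),
    scattered = array(0L, c(n_radial, n_angles, n_slices)),
    random = array(0L, c(n_radial, n_angles, n_slices)))
  if (nrow(p)) {
    # identical-crystal hits define no line of response and are dropped
    keep <- abs(p$ring_a - p$ring_b) <= max_ring_difference &
      !(p$ring_a == p$ring_b & p$az_a == p$az_b)
    p <- p[keep, ]
  }
  if (nrow(p)) {
    co <- lor_coordinates(scanner, p$ring_a, p$az_a, p$ring_b, p$az_b)
    center <- (n_radial + 1L) / 2L       # 1-based central bin
    rbin <- round(co$s / radial_bin_mm) + center
    abin <- floor(co$phi / (pi / n_angles)) + 1L
    abin[abin > n_angles] <- n_angles
    slice <- p$ring_a + p$ring_b + 1L    # 1-based
    ok <- !is.na(rbin) & rbin >= 1 & rbin <= n_radial
    lin <- rbin[ok] + n_radial * (abin[ok] - 1L) +
      n_radial * n_angles * (slice[ok] - 1L)
    kind <- p$kind[ok]
    add <- function(cube, sel) {
      if (!any(sel)) return(cube)
      tb <- tabulate(lin[sel], nbins = n_radial * n_angles * n_slices)
      cube + array(tb, dim(cube))
    }
    cubes$prompt <- add(cubes$prompt, rep(TRUE, length(lin)))
    cubes$true <- add(cubes$true, kind == "true")
    cubes$scattered <- add(cubes$scattered, kind == "scattered")
    cubes$random <- add(cubes$random, kind == "random")
  }
  structure(list(
    counts = cubes,
    radial_bin_mm = radial_bin_mm,
    n_radial = n_radial, n_angles = n_angles, n_slices = n_slices,
    slice_pitch_mm = scanner$crystal_axial_pitch_mm / 2,
    scanner_name = scanner$name,
    t_acq_s = lm$t_acq_s
  ), class = "sinogram2d_set")
}

#' @export
print.sinogram2d_set <- function(x, ...) {
  cat(sprintf(
    "<sinogram2d_set> %d radial x %d angles x %d slices (bin %.3f mm), %d prompts\n",
    x$n_radial, x$n_angles, x$n_slices, x$radial_bin_mm,
    sum(x$counts$prompt)))
  invisible(x)
}

#' Export a sinogram set to per-slice CSV files plus a JSON sidecar
#'
#' Each slice of the chosen cube is written as `<prefix>_slice<k>.csv`
#' (radial x angle counts) and the grid geometry and provenance go to
#' `<prefix>.json`.
#'
#' @param sino A `sinogram2d_set`.
#' @param prefix Output path prefix.
#' @param cube Which cube to export.
#' @param slices Slice indices (1-based; default all non-empty).
#' @export
export_sinogram_csv <- function(sino, prefix, cube = "prompt",
                                slices = NULL) {
  cb <- sino$counts[[cube]]
  if (is.null(slices))
    slices <- which(apply(cb, 3, sum) > 0)
  for (k in slices) {
    utils::write.csv(cb[, , k],
                     sprintf("%s_slice%03d.csv", prefix, k),
                     row.names = FALSE)
  }
  meta <- sino[setdiff(names(sino), "counts")]
  jsonlite::write_json(meta, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
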