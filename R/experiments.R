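# Study drivers: taper-angle optimization, LET / radial-offset / FOV
# characterization sweeps, cone-vs-EVC correlation, and the relative-
# difference reporting convention.

#' Is a source offset feasible for a segment?
#'
#' The study convention: an offset is only acquired when it is smaller
#' than the segment's minimum diameter (in mm) — e.g. the 20 mm offset is
#' skipped for a mouse-sized segment whose minimum diameter is 20 mm.
#'
#' @param segment A `fov_segment`.
#' @param radial_offset_mm Offset, mm.
#' @return TRUE/FALSE.
#' @export
offset_feasible <- function(segment, radial_offset_mm) {
  radial_offset_mm < segment$min_diameter * 10
}

#' Taper-angle optimization sweep
#'
#' For each taper angle, builds the cone with the given end diameters,
#' simulates a central line source running the full phantom length, and
#' runs the NEMA chain; the matched EVC cylinder is simulated under the
#' same conditions. The scanner FOV is centered at the axial position
#' where the cone diameter equals the supplied EVC diameter (clamped so
#' the FOV fits inside the phantom), which realizes the EVC definition —
#' the cylinder diameter equals the cone diameter at the middle of the
#' axial FOV — for every angle; at 9 degrees with the default diameters
#' this is the phantom midpoint.
#'
#' @param angles_deg Taper angles, degrees.
#' @param scanner A `scanner_spec` (X-PET class by default).
#' @param evc_diameters_cm EVC diameter per angle, cm (recycled).
#' @param min_diameter,max_diameter Cone end diameters, cm.
#' @param n_pairs Pairs per configuration.
#' @param seed Base seed; each configuration uses a distinct derived
#'   seed so re-running the sweep is bit-reproducible.
#' @param lets_kev Lower thresholds analyzed.
#' @param include_evc Also simulate each angle's EVC cylinder (needed for
#'   the cone-vs-EVC profile comparison; the SF ordering study uses the
#'   cones alone).
#' @return A list of class `sweep_result` with a `table` (data.table:
#'   angle, variant, LET, SF, SF truth, NECR, rates, counts, SE of SF)
#'   and `profiles` (per-slice SF profile per run) plus provenance.
#' @export
taper_sweep <- function(angles_deg = c(5, 7, 9, 11),
                        scanner = scanner_xpet(),
                        evc_diameters_cm = c(5.5, 5, 4.5, 4),
                        min_diameter = 2, max_diameter = 7,
                        n_pairs = 2e6, seed = 1,
                        lets_kev = scanner$let_kev,
                        include_evc = TRUE) {
  evc_diameters_cm <- rep_len(evc_diameters_cm, length(angles_deg))
  afov_cm <- scanner$axial_fov_mm / 10
  rows <- list(); profiles <- list()
  for (i in seq_along(angles_deg)) {
    th <- angles_deg[i]
    cone <- phantom_spec("cone", min_diameter, max_diameter, theta_deg = th)
    # FOV centered where the cone diameter equals the EVC diameter
    mid <- (evc_diameters_cm[i] - min_diameter) /
      (2 * tan(th * pi / 180))
    mid <- min(max(mid, afov_cm / 2), cone$length - afov_cm / 2)
    seg <- fov_segment("taper_center", mid - afov_cm / 2, mid + afov_cm / 2,
                       diameter_at(cone, mid - afov_cm / 2),
                       diameter_at(cone, mid + afov_cm / 2))
    evc <- evc_phantom(list(diameter = evc_diameters_cm[i],
                            length = afov_cm))
    eseg <- fov_segment("evc", 0, afov_cm, evc$min_diameter,
                        evc$max_diameter)
    for (variant in if (include_evc) c("cone", "evc") else "cone") {
      ph <- if (variant == "cone") cone else evc
      sg <- if (variant == "cone") seg else eseg
      run <- simulate_acquisition(
        scanner, ph, sg, radial_offset_mm = 0, n_pairs = n_pairs,
        lets_kev = lets_kev,
        source_z_range = c(0, ph$length),   # line through the whole phantom
        seed = seed + 1000L * i + 100L * (variant == "evc"))
      for (let in names(run$per_let)) {
        rows[[length(rows) + 1L]] <-
          .sweep_row(run, let, angle = th, variant = variant,
                     segment = sg$name, offset = 0)
        profiles[[sprintf("theta%02d_%s_let%s", th, variant, let)]] <-
          run$per_let[[let]]$result$per_slice
      }
    }
  }
  structure(list(table = data.table::rbindlist(rows), profiles = profiles,
                 config = list(angles_deg = angles_deg,
                               evc_diameters_cm = evc_diameters_cm,
                               n_pairs = n_pairs, seed = seed)),
            class = "sweep_result")
}

.sweep_row <- function(run, let, ...) {
  e <- run$per_let[[let]]
  s <- e$result$system
  n_ts <- e$n_true + e$n_scattered
  data.table::data.table(
    ...,
    let_kev = as.numeric(let),
    SF = s$SF, SF_truth = e$result$sf_truth,
    SF_se = sqrt(pmax(s$SF * (1 - s$SF), 0) / max(n_ts, 1)),
    NECR_system = s$NECR_system, NECR_slice_sum = s$NECR_slice_sum,
    R_tot = s$R_tot, R_true = s$R_true, R_scatter = s$R_scatter,
    n_coincidences = e$n_coincidences,
    n_true = e$n_true, n_scattered = e$n_scattered, n_random = e$n_random)
}

#' Full characterization sweep over offsets, thresholds and segments
#'
#' Simulates the cone phantom for every feasible (segment, offset) cell
#' of the grid — one transport per cell, re-windowed at every LET — and
#' optionally the matching EVC cylinder of each segment. Infeasible
#' cells (offset not smaller than the segment's minimum diameter) are
#' skipped and listed in `skipped`.
#'
#' @param scanner A `scanner_spec`.
#' @param phantom Cone `phantom_spec` (default: the fabricated phantom).
#' @param offsets_mm Source radial offsets, mm.
#' @param lets_kev Lower thresholds, keV.
#' @param segments List of `fov_segment`s (default: the three FOVs).
#' @param include_evc Also run each segment's EVC cylinder.
#' @param n_pairs Pairs per cell.
#' @param seed Base seed (distinct derived seed per cell).
#' @return A `sweep_result` (see [taper_sweep()]) whose table is keyed by
#'   (variant, segment, offset, LET); `skipped` records skipped cells.
#' @export
characterization_sweep <- function(scanner,
                                   phantom = default_cone_phantom(),
                                   offsets_mm = c(0, 10, 15, 20),
                                   lets_kev = c(250, 350, 425),
                                   segments = fov_segments(
                                     phantom, scanner$axial_fov_mm / 10),
                                   include_evc = TRUE,
                                   n_pairs = 2e6, seed = 1) {
  rows <- list(); profiles <- list(); skipped <- list()
  afov_cm <- scanner$axial_fov_mm / 10
  cell <- 0L
  for (si in seq_along(segments)) {
    seg <- segments[[si]]
    evc <- evc_phantom(evc_of(seg))
    eseg <- fov_segment(seg$name, 0, afov_cm, evc$min_diameter,
                        evc$max_diameter)
    for (off in offsets_mm) {
      if (!offset_feasible(seg, off)) {
        skipped[[length(skipped) + 1L]] <- data.table::data.table(
          segment = seg$name, offset = off,
          reason = sprintf("offset %g mm >= minimum diameter %g mm",
                           off, seg$min_diameter * 10))
        next
      }
      variants <- if (include_evc) c("cone", "evc") else "cone"
      for (variant in variants) {
        cell <- cell + 1L
        ph <- if (variant == "cone") phantom else evc
        sg <- if (variant == "cone") seg else eseg
        if (variant == "evc" &&
            !offset_feasible(sg, off)) next
        run <- simulate_acquisition(
          scanner, ph, sg, radial_offset_mm = off, n_pairs = n_pairs,
          lets_kev = lets_kev, seed = seed + 97L * cell)
        for (let in names(run$per_let)) {
          rows[[length(rows) + 1L]] <-
            .sweep_row(run, let, variant = variant, segment = seg$name,
                       offset = off)
          profiles[[sprintf("%s_%s_off%02d_let%s", variant, seg$name,
                            off, let)]] <-
            run$per_let[[let]]$result$per_slice
        }
      }
    }
  }
  structure(list(table = data.table::rbindlist(rows), profiles = profiles,
                 skipped = if (length(skipped))
                   data.table::rbindlist(skipped) else NULL,
                 config = list(scanner = scanner$name,
                               offsets_mm = offsets_mm,
                               lets_kev = lets_kev,
                               n_pairs = n_pairs, seed = seed)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d cells\n", nrow(x$table)))
  print(x$table)
  invisible(x)
}

#' Cone-vs-EVC correlation of a metric across offsets
#'
#' Squared Pearson correlation between the cone-phantom and EVC-phantom
#' values of a metric (SF or NECR), computed across source offsets for
#' each (segment, LET) cell of a characterization sweep.
#'
#' @param sweep A `sweep_result` containing both variants.
#' @param metric Column to correlate (`"SF"` or `"NECR_system"`).
#' @return data.table with segment, LET, n points and `r_squared`.
#' @export
cone_vs_evc_correlation <- function(sweep, metric = c("SF", "NECR_system")) {
  metric <- match.arg(metric)
  tb <- sweep$table
  wide <- data.table::dcast(
    tb[, c("variant", "segment", "offset", "let_kev", metric),
       with = FALSE],
    segment + let_kev + offset ~ variant, value.var = metric)
  out <- wide[, {
    ok <- stats::complete.cases(.SD[, c("cone", "evc")])
    if (sum(ok) < 3)
      stop("fewer than 3 paired offsets: correlation undefined",
           call. = FALSE)
    list(n = sum(ok),
         r_squared = stats::cor(.SD$cone[ok], .SD$evc[ok])^2)
  }, by = c("segment", "let_kev")]
  out[]
}

#' Percentage difference relative to the mean
#'
#' `|a - b| / ((a + b) / 2) x 100`: the convention used to compare two
#' estimates of the same quantity.
#'
#' @param a,b Values with `a + b != 0`.
#' @return Percent difference.
#' @export
relative_difference <- function(a, b) {
  if (any(a + b == 0)) stop("mean of the pair is zero", call. = FALSE)
  abs(a - b) / ((a + b) / 2) * 100
}
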