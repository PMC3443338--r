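#' Simulate one phantom acquisition end to end
#'
#' Runs the full chain for one configuration: emit back-to-back pairs
#' from a line source, transport them through the phantom, detect singles
#' on the crystal ring (shared energy-blur draws), then for each
#' requested lower energy threshold re-window the same singles stream,
#' sort coincidences, rebin with SSRB and run the NEMA estimator.
#' Re-windowing a single stream makes threshold sweeps variance-free
#' comparisons.
#'
#' @param scanner A `scanner_spec`.
#' @param phantom A `phantom_spec` (or `NULL` for an in-air run).
#' @param segment `fov_segment` the scanner covers (its length must equal
#'   the scanner axial FOV).
#' @param radial_offset_mm Line-source offset, mm.
#' @param n_pairs Number of annihilation pairs.
#' @param lets_kev Lower energy thresholds to analyze, keV.
#' @param seed Integer RNG seed (one seed fixes the whole run).
#' @param activity_bq Source activity (low-activity default).
#' @param source_z_range Axial extent of the active line, cm (phantom
#'   frame); default is the segment range. A physical line source runs
#'   through the whole phantom, so full-length studies pass
#'   `c(0, phantom$length)`; the range is always clipped to where the
#'   line lies inside the material.
#' @param material Scattering material (default high-density
#'   polyethylene).
#' @param keep_events If TRUE, attach singles and list-mode tables to the
#'   result (memory-heavy at large `n_pairs`).
#' @return A list of class `acquisition_result`: `per_let` — named list
#'   (one entry per LET) each holding `result` (`count_rate_result`),
#'   `n_coincidences`, and counts by truth kind; plus `config`
#'   provenance.
#' @export
simulate_acquisition <- function(scanner, phantom, segment,
                                 radial_offset_mm = 0,
                                 n_pairs = 2e6,
                                 lets_kev = scanner$let_kev,
                                 seed = 1,
                                 activity_bq = 1e5,
                                 source_z_range = NULL,
                                 material = material_polyethylene(),
                                 keep_events = FALSE) {
  stopifnot(abs((segment$z_end - segment$z_start) -
                  scanner$axial_fov_mm / 10) < 1e-6)
  set.seed(seed)
  if (is.null(source_z_range))
    source_z_range <- c(segment$z_start, segment$z_end)
  zr <- if (is.null(phantom)) {
    source_z_range
  } else {
    clip_line_to_phantom(phantom, radial_offset_mm,
                         source_z_range[1], source_z_range[2])
  }
  if (is.null(zr))
    stop("line source does not fit inside the phantom over this segment",
         call. = FALSE)
  src <- line_source(radial_offset_mm, zr[1], zr[2],
                     activity_bq = activity_bq)
  em <- emit_pairs(src, n_pairs)
  if (!is.null(phantom))
    em$photons <- transport_photons(em$photons, phantom, material)
  z_center <- (segment$z_start + segment$z_end) / 2
  singles <- detect_photons(em$photons, em$events, scanner, z_center)
  t_acq_s <- max(em$events$time_ns) * 1e-9
  per_let <- list()
  for (let in lets_kev) {
    acc <- apply_energy_window(singles, let, scanner$uet_kev)
    lm <- sort_coincidences(acc, scanner$coincidence_window_ns,
                            t_acq_s = t_acq_s)
    sino <- ssrb(lm, scanner)
    res <- if (is.null(phantom)) {
      nema_on_air(sino)
    } else {
      nema_sf_pipeline(sino, phantom, segment)
    }
    kinds <- table(factor(lm$pairs$kind,
                          levels = c("true", "scattered", "random")))
    entry <- list(result = res,
                  n_coincidences = nrow(lm$pairs),
                  n_true = kinds[["true"]],
                  n_scattered = kinds[["scattered"]],
                  n_random = kinds[["random"]])
    if (keep_events) entry$listmode <- lm
    per_let[[as.character(let)]] <- entry
  }
  out <- list(per_let = per_let,
              config = list(scanner = scanner$name,
                            phantom = if (is.null(phantom)) "none" else
                              sprintf("%s d=%g-%g theta=%g",
                                      phantom$shape, phantom$min_diameter,
                                      phantom$max_diameter,
                                      phantom$theta_deg),
                            segment = segment$name,
                            offset_mm = radial_offset_mm,
                            n_pairs = n_pairs, seed = seed,
                            activity_bq = activity_bq,
                            source_z = zr))
  if (keep_events) out$singles <- singles
  class(out) <- "acquisition_result"
  out
}

# NEMA chain without a phantom (in-air runs, e.g. vacuum validation):
# no edge mask is meaningful, so only alignment/sum/split run per slice.
nema_on_air <- function(sino, band_halfwidth_mm = 7) {
  fake_seg <- structure(list(name = "air", z_start = 0,
                             z_end = sino$n_slices), class = "fov_segment")
  ns <- sino$n_slices
  c_tot <- c_true <- c_scat <- numeric(ns)
  for (k in seq_len(ns)) {
    sl <- sino$counts$prompt[, , k]
    tot <- sum(sl)
    c_tot[k] <- tot
    if (tot == 0) next
    prof <- sum_projection(align_projections(sl))
    sp <- scatter_true_split(prof, sino$radial_bin_mm, band_halfwidth_mm)
    c_true[k] <- sp$c_true
    c_scat[k] <- sp$c_scatter
  }
  t_acq <- sino$t_acq_s
  R_true <- sum(c_true) / t_acq
  R_tot <- sum(c_tot) / t_acq
  R_scat <- sum(c_scat) / t_acq
  truth_true <- sum(sino$counts$true)
  truth_scat <- sum(sino$counts$scattered)
  structure(list(
    per_slice = data.table::data.table(
      slice = seq_len(ns), C_tot = c_tot,
      R_tot = c_tot / t_acq, R_true = c_true / t_acq,
      R_scatter = c_scat / t_acq,
      SF = ifelse(c_tot > 0, c_scat / pmax(c_true + c_scat, 1), NA),
      NECR = ifelse(c_tot > 0, (c_true / t_acq)^2 /
                      pmax(c_tot / t_acq, .Machine$double.eps), 0)),
    system = data.table::data.table(
      R_tot = R_tot, R_true = R_true, R_scatter = R_scat,
      SF = scatter_fraction(R_true, R_scat),
      NECR_system = necr(R_true, R_tot),
      NECR_slice_sum = sum(ifelse(c_tot > 0, (c_true / t_acq)^2 /
                                    pmax(c_tot / t_acq,
                                         .Machine$double.eps), 0)),
      R_random_truth = sum(sino$counts$random) / t_acq),
    sf_truth = if (truth_true + truth_scat > 0)
      scatter_fraction(truth_true, truth_scat) else NA_real_,
    t_acq_s = t_acq), class = "count_rate_result")
}

#' Simulate the absolute-sensitivity measurement
#'
#' A point source at the center of the scanner FOV in air: every emitted
#' pair travels unscattered, and the crystal interaction-probability
#' detection model is enabled so absolute efficiency is meaningful.
#' `S_i = trues / n_decays` (counts/s per Bq) and
#' `S_a = S_i / 0.906 x 100`.
#'
#' @param scanner A `scanner_spec`.
#' @param n_pairs Number of decays to simulate.
#' @param seed RNG seed.
#' @param activity_bq Source activity.
#' @return List with `s_i` (counts/s/Bq) and `s_a` (percent) and the true
#'   coincidence count.
#' @export
simulate_sensitivity <- function(scanner, n_pairs = 1e6, seed = 1,
                                 activity_bq = 1e5) {
  set.seed(seed)
  src <- line_source(0, -1e-6, 1e-6, activity_bq = activity_bq,
                     isotope = "Na-22 point")
  em <- emit_pairs(src, n_pairs)
  singles <- detect_photons(em$photons, em$events, scanner, z_center = 0,
                            use_interaction_prob = TRUE)
  acc <- apply_energy_window(singles, scanner$let_kev, scanner$uet_kev)
  lm <- sort_coincidences(acc, scanner$coincidence_window_ns,
                          t_acq_s = max(em$events$time_ns) * 1e-9)
  n_true <- sum(lm$pairs$kind == "true")
  s_i <- n_true / n_pairs
  list(s_i = s_i, s_a = absolute_sensitivity(s_i), n_true = n_true)
}
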