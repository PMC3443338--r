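# a noiseless scanner: no energy blur, no timing blur
noiseless_scanner <- function(...) {
  scanner_spec("ideal", ring_inner_diameter_mm = 165, crystals_per_ring = 240,
               n_rings = 48, axial_fov_mm = 116, crystal_depth_mm = 9.4,
               energy_resolution = 0, timing_resolution_ns = 0, ...)
}

one_photon <- function(E = 511, dir = c(1, 0, 0), pos = c(0, 0, 0),
                       scatters = 0L) {
  data.table::data.table(id = 1L, x = pos[1], y = pos[2], z = pos[3],
                         dx = dir[1], dy = dir[2], dz = dir[3],
                         energy_kev = E, n_scatters = scatters, alive = TRUE)
}
one_event <- data.table::data.table(id = 1L, time_ns = 0, x = 0, y = 0, z = 0)

test_that("a photon along +x from the center is detected at azimuth 0", {
  sc <- noiseless_scanner()
  s <- detect_photons(one_photon(), one_event, sc, z_center = 0)
  expect_equal(nrow(s), 1L)
  expect_equal(s$azimuth, 0L)
  expect_equal(s$ring, 24L)
  expect_equal(s$energy_kev, 511)
  acc <- apply_energy_window(s, 250, 750)
  expect_equal(nrow(acc), 1L)
})

test_that("the energy window rejects out-of-window singles deterministically", {
  sc <- noiseless_scanner()
  s <- detect_photons(one_photon(E = 200), one_event, sc, z_center = 0)
  expect_equal(nrow(apply_energy_window(s, 250, 750)), 0L)
  # photon leaving along the axis never meets the ring
  s2 <- detect_photons(one_photon(dir = c(0, 0, 1)), one_event, sc, 0)
  expect_equal(nrow(s2), 0L)
})

test_that("window acceptance under blur matches the Gaussian closed form", {
  sc <- scanner_spec("blur", ring_inner_diameter_mm = 165,
                     crystals_per_ring = 240, n_rings = 48,
                     axial_fov_mm = 116, crystal_depth_mm = 9.4,
                     energy_resolution = 0.25, let_kev = 425, uet_kev = 750,
                     timing_resolution_ns = 0)
  n <- 1e5
  photons <- data.table::data.table(
    id = seq_len(n), x = 0, y = 0, z = 0, dx = 1, dy = 0, dz = 0,
    energy_kev = 511, n_scatters = 0L, alive = TRUE)
  events <- data.table::data.table(id = seq_len(n), time_ns = seq_len(n),
                                   x = 0, y = 0, z = 0)
  set.seed(17)
  s <- detect_photons(photons, events, sc, z_center = 0)
  acc <- apply_energy_window(s, 425, 750)
  sigma <- 0.25 * 511 / 2.3548
  p_exp <- stats::pnorm((750 - 511) / sigma) - stats::pnorm((425 - 511) / sigma)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(nrow(acc) / n - p_exp), 3 * se)
})

test_that("re-windowing at a higher threshold never adds scattered singles", {
  cone <- default_cone_phantom()
  sc <- scanner_xpet()
  segs <- fov_segments(cone, sc$axial_fov_mm / 10)
  set.seed(3)
  src <- line_source(0, segs$FOV_rat$z_start, segs$FOV_rat$z_end)
  em <- emit_pairs(src, 5e4)
  em$photons <- transport_photons(em$photons, cone, material_polyethylene())
  singles <- detect_photons(em$photons, em$events, sc,
                            (segs$FOV_rat$z_start + segs$FOV_rat$z_end) / 2)
  n_scat <- vapply(c(250, 350, 425), function(let)
    sum(apply_energy_window(singles, let, 750)$scattered), numeric(1))
  expect_true(all(diff(n_scat) <= 0))
})

test_that("coincidence sorting pairs, discards multiples and classifies", {
  mk <- function(id, t, scat = FALSE)
    data.table::data.table(id = id, ring = 1L, azimuth = 1L,
                           energy_kev = 511, time_ns = t, scattered = scat)
  # two unscattered singles of one annihilation -> one true
  s <- rbind(mk(1L, 0), mk(1L, 5))
  lm <- sort_coincidences(s, window_ns = 12, t_acq_s = 1)
  expect_equal(lm$pairs$kind, "true")
  # one flagged scattered -> scattered
  s2 <- rbind(mk(2L, 0), mk(2L, 5, scat = TRUE))
  expect_equal(sort_coincidences(s2, 12, 1)$pairs$kind, "scattered")
  # different annihilations -> random
  s3 <- rbind(mk(3L, 0), mk(4L, 5))
  expect_equal(sort_coincidences(s3, 12, 1)$pairs$kind, "random")
  # three singles in one window -> all discarded
  s4 <- rbind(mk(5L, 0), mk(5L, 4), mk(6L, 8))
  expect_equal(nrow(sort_coincidences(s4, 12, 1)$pairs), 0L)
  expect_error(sort_coincidences(mk(1L, c(5, 0)), 12, 1), "time-ordered")
})

test_that("a 12-single stream reproduces brute-force window enumeration", {
  # hand-built times: isolated single, clean pair, triple (discarded),
  # chained cluster where the window slides, and a trailing pair
  times <- c(0, 100, 105, 300, 304, 308, 500, 511, 523, 534, 900, 908)
  ids <- c(1L, 2L, 2L, 3L, 3L, 4L, 5L, 5L, 6L, 6L, 7L, 7L)
  singles <- data.table::data.table(
    id = ids, ring = 1L, azimuth = 1L, energy_kev = 511,
    time_ns = times, scattered = FALSE)
  lm <- sort_coincidences(singles, window_ns = 12, t_acq_s = 1)
  ref <- sort_coincidences_bruteforce(times, 12)
  expect_equal(nrow(lm$pairs), length(ref))
  ref_starts <- vapply(ref, function(p) times[p[1]], numeric(1))
  expect_equal(sort(lm$pairs$time_ns), sort(ref_starts))
  # classification bookkeeping: true + scattered + random = total
  k <- table(lm$pairs$kind)
  expect_equal(sum(k), nrow(lm$pairs))
})

test_that("low activity makes randoms vanish", {
  cone <- default_cone_phantom()
  sc <- scanner_xpet()
  segs <- fov_segments(cone, sc$axial_fov_mm / 10)
  run <- simulate_acquisition(sc, cone, segs$FOV_rat, 0, n_pairs = 5e4,
                              lets_kev = 250, seed = 4)
  e <- run$per_let[["250"]]
  expect_lt(e$n_random / max(e$n_coincidences, 1), 0.002)
  # label bookkeeping is exact
  expect_equal(e$n_true + e$n_scattered + e$n_random, e$n_coincidences)
})
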