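test_that("taper relation gives the fabricated phantom lengths", {
  expect_equal(round(phantom_length(2, 7, 9), 1), 15.8)
  expect_equal(round(phantom_length(2, 7, 5), 1), 28.6)
  expect_equal(phantom_length(5, 5, 45), 0)
  expect_error(phantom_length(2, 7, 0), "invalid geometry")
  expect_error(phantom_length(2, 7, -3), "invalid geometry")
})

test_that("taper relation round-trips through the diameter profile", {
  for (th in c(5, 7, 9, 11)) {
    L <- phantom_length(2, 7, th)
    ph <- phantom_spec("cone", 2, 7, theta_deg = th)
    expect_equal(diameter_at(ph, L), 7, tolerance = 1e-9)
  }
})

test_that("diameter profile is linear with clamped ends", {
  ph <- default_cone_phantom()
  expect_equal(diameter_at(ph, ph$length), 7.0)
  expect_equal(diameter_at(ph, ph$length / 2), 4.5)
  # direct evaluation 2 + 2 * 7.5 * tan(9 deg)
  expect_equal(diameter_at(ph, 7.5), 2 + 15 * tan(9 * pi / 180),
               tolerance = 1e-12)
  expect_error(diameter_at(ph, -1), "out of range")
  expect_error(diameter_at(ph, ph$length + 1), "out of range")
})

test_that("phantom_spec validates its geometry", {
  expect_error(phantom_spec("cone", 2, 7, theta_deg = 9, length = 20),
               "inconsistent")
  expect_error(phantom_spec("cylinder", 2, 7, length = 10), "equal end")
  cyl <- phantom_spec("cylinder", 4.5, 4.5, length = 11.6)
  expect_identical(cyl$theta_deg, 0)
  def <- default_cone_phantom()
  expect_equal(def$length, phantom_length(2, 7, 9))
  expect_equal(def$density, 0.96)
  expect_equal(def$hole_offsets_mm, c(0, 10, 15, 20))
})

test_that("FOV segments cover the phantom ends and their EVC follows the midpoint rule", {
  ph <- default_cone_phantom()
  # wide axial FOV (X-PET class)
  segs <- fov_segments(ph, 11.6)
  expect_equal(segs$FOV_mouse$z_start, 0)
  expect_equal(segs$FOV_mouse$min_diameter, 2.0)
  expect_equal(segs$FOV_rabbit$z_end, ph$length)
  expect_equal(segs$FOV_rabbit$max_diameter, 7.0)
  # narrow axial FOV (LabPET class)
  segs2 <- fov_segments(ph, 7.5)
  expect_equal(segs2$FOV_rabbit$max_diameter, 7.0)
  expect_equal(abs(segs2$FOV_rat$z_start + segs2$FOV_rat$z_end) / 2,
               ph$length / 2, tolerance = 1e-9)
  expect_error(fov_segments(ph, 20), "exceeds phantom length")
  # cylinder: all three segments see the same diameter
  cyl <- phantom_spec("cylinder", 4.5, 4.5, length = 15)
  cs <- fov_segments(cyl, 7.5)
  for (s in cs) {
    expect_equal(s$min_diameter, 4.5)
    expect_equal(s$max_diameter, 4.5)
  }
  # EVC: diameter at the middle of the FOV = mean of the end diameters
  expect_equal(evc_of(fov_segment("FOV_rat", 0, 7.5, 3, 6))$diameter, 4.5)
  expect_equal(evc_of(fov_segment("FOV_rabbit", 0, 7.5, 4.5, 7))$diameter,
               5.75)  # reported rounded to 5.8
  expect_equal(evc_of(fov_segment("x", 0, 7.5, 4, 4))$diameter, 4)
  expect_equal(evc_of(segs$FOV_mouse)$length, 11.6)
})

test_that("chord lengths match simple closed forms", {
  cyl <- phantom_spec("cylinder", 4.5, 4.5, length = 10)
  # ray through the axis, perpendicular to it
  expect_equal(chord_length(cyl, c(-10, 0, 5), c(1, 0, 0)), 4.5,
               tolerance = 1e-9)
  # ray down the center of the default cone
  cone <- default_cone_phantom()
  expect_equal(chord_length(cone, c(0, 0, -1), c(0, 0, 1)), cone$length,
               tolerance = 1e-9)
  # miss entirely
  expect_equal(chord_length(cone, c(10, 10, 5), c(0, 0, 1)), 0)
  expect_error(chord_length(cone, c(0, 0, 0), c(1, 1, 0)), "unit vector")
})

test_that("chord lengths agree with a step-marching oracle on random rays", {
  set.seed(42)
  cone <- default_cone_phantom()
  for (i in 1:20) {
    origin <- c(runif(1, -2, 2), runif(1, -2, 2), runif(1, -2, 18))
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    expect_equal(chord_length(cone, origin, d),
                 chord_length_marching(cone, origin, d),
                 tolerance = 5e-3)
  }
})

test_that("chord length is reversal-symmetric, bounded, and continuous in the taper", {
  set.seed(7)
  cone <- default_cone_phantom()
  diag_len <- sqrt(cone$length^2 + cone$max_diameter^2)
  for (i in 1:10) {
    origin <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, 0, 15.8))
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    cl <- chord_length(cone, origin, d)
    expect_equal(cl, chord_length(cone, origin, -d), tolerance = 1e-9)
    expect_lte(cl, diag_len + 1e-9)
  }
  # theta -> 0 converges to the cylinder
  thin <- phantom_spec("cone", 4.5, 4.5 + 2 * 10 * tan(1e-4 * pi / 180),
                       theta_deg = 1e-4)
  cyl <- phantom_spec("cylinder", 4.5, 4.5, length = thin$length)
  for (i in 1:5) {
    origin <- c(runif(1, -1, 1), runif(1, -1, 1), runif(1, 1, 9))
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    a <- chord_length(thin, origin, d)
    b <- chord_length(cyl, origin, d)
    if (b > 0) expect_lt(abs(a - b) / b, 1e-3)
  }
})

test_that("phantom configuration round-trips through YAML", {
  ph <- default_cone_phantom()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_config(ph, f)
  ph2 <- read_phantom_config(f)
  expect_equal(ph2$length, ph$length)
  expect_equal(ph2$theta_deg, ph$theta_deg)
  expect_equal(ph2$hole_offsets_mm, ph$hole_offsets_mm)
})
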