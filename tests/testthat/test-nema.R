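# minimal sinogram2d_set built by hand
sino_of <- function(cube_prompt, radial_bin_mm = 1, slice_pitch_mm = 10,
                    t_acq_s = 1) {
  structure(list(
    counts = list(prompt = cube_prompt,
                  true = array(0L, dim(cube_prompt)),
                  scattered = array(0L, dim(cube_prompt)),
                  random = array(0L, dim(cube_prompt))),
    radial_bin_mm = radial_bin_mm,
    n_radial = dim(cube_prompt)[1], n_angles = dim(cube_prompt)[2],
    n_slices = dim(cube_prompt)[3],
    slice_pitch_mm = slice_pitch_mm, scanner_name = "toy",
    t_acq_s = t_acq_s), class = "sinogram2d_set")
}

test_that("edge masking zeroes bins beyond radius + margin, slice by slice", {
  # one slice, 81 radial bins at 1 mm: cylinder radius 22.5 mm, margin 8
  cube <- array(1L, c(81, 4, 1))
  sg <- sino_of(cube, radial_bin_mm = 1, slice_pitch_mm = 100)
  cyl <- phantom_spec("cylinder", 4.5, 4.5, length = 10)
  seg <- fov_segment("whole", 0, 10, 4.5, 4.5)
  masked <- mask_beyond_edge(sg, cyl, seg, margin_mm = 8)
  prof <- masked$counts$prompt[, 1, 1]
  s_mm <- (1:81) - 41
  # hand rule: survivors are the 61 bins with |s| <= 30.5 (bin centers
  # -30..30 mm); the 20 outer bins are zeroed
  expect_equal(which(prof > 0), which(abs(s_mm) <= 30.5))
  expect_equal(sum(prof), 61)
  # infinite margin: identity
  same <- mask_beyond_edge(sg, cyl, seg, margin_mm = Inf)
  expect_equal(same$counts$prompt, cube)
  # all-zero stays all-zero
  z <- sino_of(array(0L, c(81, 4, 1)), slice_pitch_mm = 100)
  expect_equal(sum(mask_beyond_edge(z, cyl, seg, 8)$counts$prompt), 0)
})

test_that("projection alignment centers each angular row on its maximum", {
  m <- matrix(0, 11, 3)
  m[6, 1] <- 10                 # already centered: unchanged
  m[9, 2] <- 7; m[4, 2] <- 2    # max at center + 3: shifted left by 3
  m[2, 3] <- 5                  # wraps around
  a <- align_projections(m)
  expect_equal(a[, 1], m[, 1])
  expect_equal(which.max(a[, 2]), 6L)
  expect_equal(a[1, 2], 2)      # companion value carried along circularly
  expect_equal(which.max(a[, 3]), 6L)
  # counts conserved per row
  expect_equal(colSums(a), colSums(m))
  expect_error(align_projections(matrix(0, 10, 2)), "odd")
})

test_that("sum projection conserves counts", {
  m <- matrix(1:15, 5, 3)
  expect_equal(sum_projection(m), rowSums(m))
  expect_equal(sum(sum_projection(m)), sum(m))
  # single-angle input: identity
  v <- matrix(c(0, 2, 9, 2, 0), 5, 1)
  expect_equal(sum_projection(v), as.vector(v))
  # hand-summed 3 x 5 toy slice
  toy <- matrix(c(1, 0, 2,  0, 3, 1,  2, 2, 2,  1, 1, 0,  0, 0, 4), 3, 5)
  expect_equal(sum_projection(toy), c(1 + 0 + 2 + 1 + 0,
                                      0 + 3 + 2 + 1 + 0,
                                      2 + 1 + 2 + 0 + 4))
})

test_that("the 14 mm band split separates trues from scatter", {
  # constant profile: the line equals the profile, no trues
  sp <- scatter_true_split(rep(5, 11), bin_width_mm = 2)
  expect_equal(sp$c_true, 0)
  expect_equal(sp$c_scatter, 55)
  # delta peak on zero background: all trues
  d <- rep(0, 11); d[6] <- 40
  sp2 <- scatter_true_split(d, bin_width_mm = 2)
  expect_equal(sp2$c_true, 40)
  expect_equal(sp2$c_scatter, 0)
  # the hand-worked profile: band of 3 bins, edges valued 10/10,
  # trues = 40 - 10 = 30 and the rest is scatter
  prof <- c(0, 0, 2, 2, 10, 40, 10, 2, 2, 0, 0)
  sp3 <- scatter_true_split(prof, bin_width_mm = 7)
  expect_equal(sp3$c_true, 30)
  expect_equal(sp3$c_scatter, sum(prof) - 30)
  # counts conserved up to the clamp diagnostic
  expect_equal(sp3$c_true + sp3$c_scatter, sum(prof))
  expect_error(scatter_true_split(rep(1, 3), bin_width_mm = 1), "band")
})

test_that("count-rate formulas follow their definitions", {
  er <- event_rates(c(400, 600), t_acq_s = 10)
  expect_equal(er$per_slice, c(40, 60))
  expect_equal(er$system, 100)
  expect_equal(event_rates(1000, 5)$system, 2 * event_rates(1000, 10)$system)
  expect_error(event_rates(10, 0), "positive")

  expect_equal(scatter_fraction(75, 25), 0.25)
  expect_equal(scatter_fraction(10, 0), 0)
  expect_error(scatter_fraction(0, 0), "undefined")

  expect_equal(necr(100, 200), 50)
  expect_equal(necr(200, 200), 200)  # noiseless limit
  expect_error(necr(1, 0), "positive")

  expect_equal(absolute_sensitivity(0.00906), 1.0)
  expect_equal(absolute_sensitivity(0), 0)
  expect_equal(absolute_sensitivity(0.0571), 6.30, tolerance = 2e-3)
})

test_that("counts are conserved through mask, align and sum", {
  set.seed(33)
  cube <- array(rpois(41 * 8 * 3, 2), c(41, 8, 3))
  sg <- sino_of(cube, radial_bin_mm = 1, slice_pitch_mm = 20)
  cyl <- phantom_spec("cylinder", 20, 20, length = 10)  # huge: mask no-op
  seg <- fov_segment("whole", 0, 3 * 20 * 2 / 10, 20, 20)
  masked <- mask_beyond_edge(sg, cyl, seg, margin_mm = 8)
  for (k in 1:3) {
    sl <- masked$counts$prompt[, , k]
    expect_equal(sum(sum_projection(align_projections(sl))), sum(sl))
  }
})

test_that("the pipeline reports near-zero scatter fraction without a phantom", {
  sc <- scanner_xpet()
  seg <- fov_segment("air", 0, sc$axial_fov_mm / 10, 4.5, 4.5)
  run <- simulate_acquisition(sc, NULL, seg, 0, n_pairs = 1e5,
                              lets_kev = 250, seed = 12)
  expect_lt(run$per_let[["250"]]$result$system$SF, 0.02)
})

test_that("the estimator tracks the label-based scatter fraction", {
  cone <- default_cone_phantom()
  sc <- scanner_xpet()
  segs <- fov_segments(cone, sc$axial_fov_mm / 10)
  run <- simulate_acquisition(sc, cone, segs$FOV_rat, 0, n_pairs = 2e5,
                              lets_kev = 250, seed = 14)
  r <- run$per_let[["250"]]
  expect_lt(abs(r$result$system$SF - r$result$sf_truth) / r$result$sf_truth,
            0.15)
  # bookkeeping: R_true + R_scatter equals R_tot on the masked sinogram
  s <- r$result$system
  expect_equal(s$R_true + s$R_scatter, s$R_tot, tolerance = 1e-9)
})
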