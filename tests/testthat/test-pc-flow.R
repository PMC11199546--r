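# Phase-contrast flow quantification.

test_that("phase maps linearly to velocity", {
  expect_equal(phase_to_velocity(pi, 150), 150)
  expect_equal(phase_to_velocity(0, 150), 0)
  expect_equal(phase_to_velocity(-pi / 2, 100), -50)
  ser <- make_flow_phantom(phantom_spec(5, 75, venc = 150, n_phases = 2))
  v <- phase_to_velocity(ser)
  expect_equal(dim(v), dim(ser$phase))
  expect_equal(max(v), 75, tolerance = 1e-9)
  expect_error(phase_to_velocity(pi, -3), "venc")
})

test_that("aliased velocities are unwrapped toward the ROI-median sign", {
  # a +170 cm/s pixel at VENC 150 wraps to -130; unwrap restores it
  v <- matrix(c(100, 120, -130, 110), 2, 2)
  out <- unwrap_velocity(v, venc = 150)
  expect_equal(out[1, 2], 170)
  expect_equal(out[c(1, 2, 4)], v[c(1, 2, 4)])
  # idempotent on alias-free data
  clean <- matrix(c(10, 20, -30, 40), 2, 2)
  expect_equal(unwrap_velocity(clean, 150), clean)
  expect_equal(unwrap_velocity(unwrap_velocity(v, 150), 150), out)
  # all-zero stack unchanged
  z <- array(0, c(3, 4, 4))
  expect_equal(unwrap_velocity(z, 150), z)
})

test_that("static-tissue correction removes a constant offset exactly", {
  v <- array(5, c(3, 6, 6))
  v[, 3, 3] <- 25    # vessel on top of the 5 cm/s offset
  static <- matrix(TRUE, 6, 6)
  static[3, 3] <- FALSE
  out <- correct_background_offset(v, static)
  expect_equal(out[1, 1, 1], 0)
  expect_equal(out[2, 3, 3], 20)
  # idempotent; identity at zero offset
  expect_equal(correct_background_offset(out, static), out)
  z <- array(0, c(2, 4, 4))
  expect_equal(correct_background_offset(z, matrix(TRUE, 4, 4)), z)
  expect_error(correct_background_offset(v, matrix(FALSE, 6, 6)), "static")
})

test_that("background-offset phantoms recover the offset-free flow", {
  base <- make_flow_phantom(phantom_spec(10, 25, venc = 150, n_phases = 5))
  off <- make_flow_phantom(phantom_spec(10, 25, venc = 150, n_phases = 5,
                                        background_offset = 0.1))
  f0 <- measure_flow(base, correct_offset = FALSE)$mean_flow
  f1 <- measure_flow(off, correct_offset = TRUE)$mean_flow
  expect_lt(abs(f1 - f0) / f0, 0.005)
})

test_that("flow integration follows the area x velocity rule", {
  # uniform 10 cm/s over 100 px of 1 mm^2 = 1 cm^2 -> 600 mL/min
  v <- matrix(0, 20, 20)
  roi <- matrix(FALSE, 20, 20)
  roi[1:10, 1:10] <- TRUE
  v[roi] <- 10
  fm <- integrate_flow(v, roi, pixel_spacing = 1)
  expect_equal(fm$mean_flow, 600)
  expect_equal(fm$n_pixels, 100)
  expect_equal(integrate_flow(matrix(0, 5, 5), matrix(TRUE, 5, 5),
                              1)$mean_flow, 0)
  expect_error(integrate_flow(v, matrix(FALSE, 20, 20), 1), "empty")
  expect_error(integrate_flow(v, matrix(TRUE, 4, 4), 1), "grid")
})

test_that("flow scales linearly with the phase scale (homogeneity)", {
  ph <- make_flow_phantom(phantom_spec(9, 18, venc = 150, n_phases = 4))
  f1 <- measure_flow(ph, correct_offset = FALSE)$mean_flow
  ph2 <- ph
  ph2$phase <- ph$phase * 1.75
  f2 <- measure_flow(ph2, correct_offset = FALSE)$mean_flow
  expect_equal(f2 / f1, 1.75, tolerance = 1e-9)
})

test_that("noisy phantom flow is unbiased", {
  truth <- pi * 1^2 * 20 / 2 * 60
  flows <- vapply(1:100, function(s) {
    ph <- make_flow_phantom(phantom_spec(10, 20, venc = 150, n_phases = 15,
                                         noise_sd_phase = 0.05, seed = s))
    measure_flow(ph, correct_offset = FALSE)$mean_flow
  }, numeric(1))
  expect_lt(abs(mean(flows) - truth) / truth, 0.02)
})

test_that("temporal resolution follows heart rate and phase count", {
  expect_equal(temporal_resolution(140, 15), 60000 / 140 / 15)
  expect_equal(round(temporal_resolution(140, 15), 2), 28.57)
  expect_equal(temporal_resolution(60, 1), 1000)
  expect_equal(round(temporal_resolution(120, 15), 2), 33.33)
  expect_error(temporal_resolution(0, 15), "heart_rate")
  expect_error(temporal_resolution(140, 0), "n_phases")
})

test_that("automatic ROI finds the lumen on a clean phantom", {
  ph <- make_flow_phantom(phantom_spec(8, 30, venc = 100, n_phases = 3))
  roi <- auto_roi(ph)
  # recovered mask overlaps the true lumen almost perfectly
  jaccard <- sum(roi & ph$lumen) / sum(roi | ph$lumen)
  expect_gt(jaccard, 0.9)
})
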