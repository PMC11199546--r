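# T2 relaxometry and the saturation calibration.

test_that("central-fraction erosion matches the brute-force ranking", {
  n <- 25
  xx <- matrix(rep(1:n, each = n), n, n)
  yy <- matrix(rep(1:n, times = n), n, n)
  disk <- ((xx - 13)^2 + (yy - 13)^2) <= 100
  out <- erode_to_central_fraction(disk, 0.6)
  ref <- brute_erode(disk, 0.6)
  expect_identical(out, ref)
  # area within one pixel of the target fraction, and a strict subset
  expect_lte(abs(sum(out) - 0.6 * sum(disk)), 1)
  expect_true(all(disk[out]))
  # retained pixels at least as deep as every discarded pixel
  d <- brute_dist_to_boundary(disk)
  expect_gte(min(d[out]), max(d[disk & !out]) - 1e-9)
})

test_that("erosion limits: identity at fraction 1, deepest pixel near 0", {
  m <- matrix(FALSE, 11, 11)
  m[3:9, 3:9] <- TRUE
  expect_identical(erode_to_central_fraction(m, 1), m)
  tiny <- erode_to_central_fraction(m, 1e-6)
  expect_equal(sum(tiny), 1)
  expect_true(m[tiny])          # the survivor lies inside the mask
  expect_identical(tiny, brute_erode(m, 1e-6))
  expect_error(erode_to_central_fraction(matrix(FALSE, 4, 4), 0.5), "empty")
})

test_that("erosion on irregular masks stays a subset and never grows", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(stats::runif(15 * 15) > 0.4, 15, 15)
    if (!any(m)) next
    for (f in c(0.3, 0.6, 0.9)) {
      out <- erode_to_central_fraction(m, f)
      expect_true(all(m[out]))
      expect_lte(sum(out), sum(m))
      expect_identical(out, brute_erode(m, f))
    }
  }
})

test_that("ROI means reproduce the programmed exponential decay", {
  ph <- make_t2_phantom(t2_phantom_spec(120, 200))
  mu <- mean_roi_signal(ph, ph$lumen)
  expect_equal(mu, 200 * exp(-ph$prep_times_ms / 120), tolerance = 1e-12)
  const <- ph
  const$images[] <- 7
  expect_equal(mean_roi_signal(const, const$lumen), rep(7, 6))
  single <- matrix(FALSE, dim(ph$images)[2], dim(ph$images)[3])
  single[13, 13] <- TRUE
  expect_equal(mean_roi_signal(ph, single), ph$images[, 13, 13])
  expect_error(mean_roi_signal(ph, single & FALSE), "empty")
})

test_that("noiseless T2 fits are exact and both methods agree", {
  t <- c(32, 64, 96, 128, 160, 192)
  s <- 200 * exp(-t / 120)
  it <- fit_t2(s, t, method = "iterative")
  ll <- fit_t2(s, t, method = "loglinear")
  expect_equal(it$t2_ms, 120, tolerance = 1e-9)
  expect_equal(it$s0, 200, tolerance = 1e-9)
  expect_equal(it$r_squared, 1, tolerance = 1e-12)
  expect_equal(ll$t2_ms, it$t2_ms, tolerance = 1e-9)
  expect_equal(ll$s0, it$s0, tolerance = 1e-9)
})

test_that("degenerate and invalid decays are flagged or rejected", {
  t <- c(32, 64, 96, 128, 160, 192)
  flat <- fit_t2(rep(150, 6), t)
  expect_true(flat$at_bound)
  expect_error(fit_t2(c(1, 2), c(32, 64)), "at least 3")
  expect_error(fit_t2(c(10, -1, 5, 2, 1, 0.5), t, method = "loglinear"),
               "positive")
})

test_that("T2 estimation is accurate at realistic noise", {
  t2s <- vapply(1:300, function(s) {
    ph <- make_t2_phantom(t2_phantom_spec(120, 200, noise_sd = 4, seed = s))
    core <- erode_to_central_fraction(ph$lumen, 0.6)
    fit_t2(mean_roi_signal(ph, core), ph$prep_times_ms)$t2_ms
  }, numeric(1))
  expect_lt(sqrt(mean((t2s - 120)^2)) / 120, 0.05)   # relative RMSE < 5%
  expect_lt(abs(mean(t2s) - 120) / 120, 0.01)        # bias < 1%
})

test_that("calibration inverts exactly and is monotone", {
  cal <- t2_calibration()
  expect_equal(t2_to_so2(so2_to_t2(1, cal), cal)[1], 1)
  for (y in c(0, 0.25, 0.5, 0.75, 1))
    expect_equal(as.numeric(t2_to_so2(so2_to_t2(y, cal), cal)), y,
                 tolerance = 1e-9)
  expect_equal(so2_to_t2(1, cal), cal$t2_plateau_ms)
  expect_equal(so2_to_t2(0, cal), 1 / (1 / cal$t2_plateau_ms + cal$k_rate))
  expect_lt(so2_to_t2(0.3, cal), so2_to_t2(0.7, cal))
  # hand-inverted point on an explicitly configured calibration:
  # 1/t2 - 1/250 = K * 0.25 with K = 2.5e-4 -> Y = 0.5
  cal2 <- t2_calibration(t2_plateau_ms = 250, k_rate = 2.5e-4)
  t2 <- 1 / (1 / 250 + 2.5e-4 * 0.25)
  expect_equal(as.numeric(t2_to_so2(t2, cal2)), 0.5, tolerance = 1e-12)
})

test_that("unphysical T2 values clamp within tolerance and error beyond", {
  cal <- t2_calibration(t2_plateau_ms = 250, k_rate = 0.03)
  # just above the plateau: root slightly above 1, clamped with a flag
  t2_hi <- so2_to_t2(1, cal) + 0.05
  y <- t2_to_so2(t2_hi, cal)
  expect_equal(as.numeric(y), 1)
  expect_true(attr(y, "clamped"))
  # far above the plateau: unphysical
  expect_error(t2_to_so2(400, cal), "plateau")
  expect_error(t2_to_so2(-5, cal), "t2_ms")
  # unidentifiable flat calibration
  cal0 <- t2_calibration(t2_plateau_ms = 250, k_rate = 0)
  expect_error(t2_to_so2(100, cal0), "K = 0")
  expect_equal(as.numeric(t2_to_so2(250, cal0)), 1)
  expect_error(so2_to_t2(1.4, cal), "0, 1", fixed = FALSE)
})

test_that("end-to-end oximetry recovers the programmed saturation", {
  cal <- t2_calibration()
  for (y_true in c(0.29, 0.474, 0.585, 0.8)) {
    ph <- make_t2_phantom(t2_phantom_spec(so2_to_t2(y_true, cal), 200))
    m <- measure_saturation(ph, calib = cal)
    expect_equal(m$y, y_true, tolerance = 1e-6)
  }
})
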