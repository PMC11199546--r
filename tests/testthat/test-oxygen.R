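# Fick-principle oxygen delivery, consumption and extraction.

test_that("oxygen content follows 1.36 x Hb x Y", {
  expect_equal(o2_content(98, 0.585), 77.9688)
  expect_equal(o2_content(100, 0), 0)
  expect_equal(o2_content(200, 0.5), 2 * o2_content(100, 0.5))
  expect_error(o2_content(98, 1.2), "0, 1")
  expect_error(o2_content(-1, 0.5), "hb")
})

test_that("delivery equations reproduce hand arithmetic", {
  expect_equal(fetal_do2(100, 0.8, 500), 54.4)
  expect_equal(fetal_do2(100, 0.8, 0), 0)
  expect_equal(fetal_do2(1000 / 1.36, 1, 1000), 1000)
  expect_equal(cerebral_do2(98, 0.585, 80), 6.237504)
  expect_equal(round(cerebral_do2(98, 0.585, 80), 2), 6.24)
  expect_equal(cerebral_do2(98, 0.585, 0), 0)
  # shared kernel: same formula under symbol substitution
  expect_equal(cerebral_do2(120, 0.66, 90), fetal_do2(120, 0.66, 90))
})

test_that("consumption equations reproduce hand arithmetic", {
  expect_equal(as.numeric(fetal_vo2(100, 0.8, 0.5, 400)), 16.32)
  expect_equal(as.numeric(fetal_vo2(100, 0.6, 0.6, 400)), 0)
  # algebraic identity: VO2 = DO2 - venous-side delivery
  expect_equal(as.numeric(fetal_vo2(100, 0.8, 0.5, 400)),
               fetal_do2(100, 0.8, 400) - 1.36 * 100 * 0.5 * 400 / 1000)
  expect_equal(as.numeric(cerebral_vo2(98, 0.6, 0.3, 100)), 3.9984)
  expect_equal(round(as.numeric(cerebral_vo2(98, 0.6, 0.3, 100)), 2), 4.00)
  expect_equal(as.numeric(cerebral_vo2(98, 0.45, 0.45, 100)), 0)
  expect_equal(as.numeric(cerebral_vo2(98, 0.6, 0.3, 200)),
               2 * as.numeric(cerebral_vo2(98, 0.6, 0.3, 100)))
  # negative arteriovenous difference is flagged, not clipped
  neg <- fetal_vo2(100, 0.4, 0.6, 300)
  expect_lt(as.numeric(neg), 0)
  expect_true(attr(neg, "flagged"))
})

test_that("extraction fraction and its identities", {
  expect_equal(as.numeric(extraction_fraction(0.6, 0.3)), 0.5)
  expect_equal(as.numeric(extraction_fraction(0.6, 0.6)), 0)
  expect_equal(round(as.numeric(extraction_fraction(0.585, 0.29)), 3), 0.504)
  expect_error(extraction_fraction(0, 0.3), "y_in")
  flagged <- extraction_fraction(0.4, 0.6)
  expect_true(attr(flagged, "flagged"))
  # OEF x DO2 = VO2 on matched inputs
  hb <- 98; y_in <- 0.72; y_out <- 0.31; q <- 230
  oef <- as.numeric(extraction_fraction(y_in, y_out))
  expect_equal(oef * fetal_do2(hb, y_in, q),
               as.numeric(fetal_vo2(hb, y_in, y_out, q)),
               tolerance = 1e-12)
  # VO2 <= DO2 whenever venous <= arterial
  expect_lte(as.numeric(fetal_vo2(hb, y_in, y_out, q)),
             fetal_do2(hb, y_in, q))
  expect_equal(as.numeric(fetal_vo2(hb, y_in, 0, q)), fetal_do2(hb, y_in, q))
})

test_that("weight normalisation", {
  expect_equal(normalise_per_kg(54.4, 3000), 54.4 / 3)
  expect_equal(round(normalise_per_kg(54.4, 3000), 2), 18.13)
  expect_equal(normalise_per_kg(12.5, 1000), 12.5)
  expect_equal(normalise_per_kg(10, 500), 2 * normalise_per_kg(10, 1000))
  expect_error(normalise_per_kg(10, 0), "weight")
})

test_that("the cohort oxygen-transport panel is internally consistent", {
  coh <- derive_flows_cohort(make_cohort(cohort_config(n_control = 3,
                                                       n_fgr = 2, seed = 8)))
  ox <- compute_oxygen_transport(coh)
  expect_equal(ox$fetal_do2,
               1.36 * coh$hb_g_per_l * coh$sat_UV * coh$flow_UV / 1000)
  expect_equal(ox$fetal_oef * ox$fetal_do2, ox$fetal_vo2, tolerance = 1e-12)
  expect_equal(ox$cerebral_oef * ox$cerebral_do2, ox$cerebral_vo2,
               tolerance = 1e-12)
  expect_equal(ox$fetal_do2_per_kg, ox$fetal_do2 / (coh$weight_g / 1000))
  # homogeneity of degree one in haemoglobin
  coh2 <- coh
  coh2$hb_g_per_l <- coh$hb_g_per_l * 2
  ox2 <- compute_oxygen_transport(coh2)
  expect_equal(ox2$fetal_vo2, 2 * ox$fetal_vo2, tolerance = 1e-12)
})
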