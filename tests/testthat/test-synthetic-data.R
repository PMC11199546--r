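# Generators: flow/T2 phantoms, label volumes, virtual cohorts.

test_that("flow phantom encodes velocity in phase exactly", {
  # zero flow, no offset/noise: phase identically zero
  ph0 <- make_flow_phantom(phantom_spec(6, 0, venc = 100, n_phases = 4))
  expect_true(all(ph0$phase == 0))

  # peak velocity at the encoding limit maps the centre pixel to +pi
  ph1 <- make_flow_phantom(phantom_spec(6, 150, venc = 150, n_phases = 1))
  expect_equal(max(ph1$phase), pi, tolerance = 1e-12)
  ctr <- (dim(ph1$phase)[2] + 1) / 2
  expect_identical(ph1$phase[1, ctr, ctr], pi)
})

test_that("parabolic phantom flow matches the closed-form Poiseuille value", {
  ph <- make_flow_phantom(phantom_spec(10, 20, venc = 150, n_phases = 5,
                                       pixel_spacing = 1))
  fm <- measure_flow(ph, correct_offset = FALSE)
  analytic <- pi * 1^2 * 20 / 2 * 60          # r = 10 px x 1 mm = 1 cm
  expect_lt(abs(fm$mean_flow - analytic) / analytic, 0.02)
})

test_that("phantom generators are seed-deterministic", {
  a <- make_flow_phantom(phantom_spec(8, 30, venc = 100, noise_sd_phase = 0.1,
                                      seed = 11))
  b <- make_flow_phantom(phantom_spec(8, 30, venc = 100, noise_sd_phase = 0.1,
                                      seed = 11))
  expect_identical(a$phase, b$phase)
  ta <- make_t2_phantom(t2_phantom_spec(100, 150, noise_sd = 3, seed = 5))
  tb <- make_t2_phantom(t2_phantom_spec(100, 150, noise_sd = 3, seed = 5))
  expect_identical(ta$images, tb$images)
})

test_that("T2 phantom signal follows the mono-exponential decay", {
  ph <- make_t2_phantom(t2_phantom_spec(120, 200))
  ctr <- (dim(ph$images)[2] + 1) / 2
  # third prep time is 96 ms: 200 * exp(-0.8)
  expect_equal(ph$images[3, ctr, ctr], 89.86579, tolerance = 1e-5)
  # no decay limit: t2 -> Inf reproduces s0 at the first prep time
  ph2 <- make_t2_phantom(t2_phantom_spec(1e12, 200))
  expect_equal(ph2$images[1, ctr, ctr], 200, tolerance = 1e-6)
})

test_that("phantom specs validate their inputs", {
  expect_error(phantom_spec(0, 10, venc = 100), "radius")
  expect_error(phantom_spec(5, 10, venc = -1), "venc")
  expect_error(t2_phantom_spec(-5, 100), "t2_ms")
  expect_error(t2_phantom_spec(100, 100, prep_times_ms = numeric(0)),
               "non-empty")
  expect_error(t2_phantom_spec(100, 100, prep_times_ms = c(64, 32)),
               "increasing")
})

test_that("label volumes carry the requested voxel counts", {
  seg <- make_label_volume(c(20, 20, 5), 1000, 0, voxel_size_mm = c(1, 1, 1))
  vol <- measure_volumes(seg)
  expect_equal(vol$fetal_ml, 1.0)
  expect_equal(vol$brain_ml, 0)
  seg2 <- make_label_volume(c(100, 100, 30), 276923, 40000,
                            voxel_size_mm = c(1.5, 1.5, 2))
  vol2 <- measure_volumes(seg2)
  expect_equal(vol2$fetal_ml, 276923 * 4.5 / 1000, tolerance = 1e-12)
  expect_equal(round(vol2$fetal_ml, 1), 1246.2)
  expect_error(make_label_volume(c(5, 5, 5), 200, 0), "exceed")
  expect_error(make_label_volume(c(5, 5, 5), 10, 20), "brain_voxels")
})

test_that("degenerate cohort (all SDs zero) reproduces the cell means", {
  cc <- cohort_config(n_control = 3, n_fgr = 2, seed = 1)
  cc$params$sd <- 0
  coh <- make_cohort(cc)
  p <- cc$params
  for (v in c("flow_DV", "sat_AAo", "hb_g_per_l")) {
    for (g in c("control", "FGR")) for (st in c("normoxia", "hypoxia")) {
      mu <- p$mean[p$variable == v & p$group == g & p$state == st]
      expect_equal(unique(coh[[v]][coh$group == g & coh$state == st]), mu)
    }
  }
})

test_that("cohort sample moments match the configured distribution", {
  # pool control-normoxia arterial saturation across replicate cohorts until
  # n ~ 1000; sample mean must sit within 3 SE of the configured 0.585
  vals <- unlist(lapply(1:84, function(s) {
    coh <- make_cohort(cohort_config(seed = s))
    coh$sat_AAo[coh$group == "control" & coh$state == "normoxia"]
  }))
  se <- 0.075 / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.585), 3 * se)
})

test_that("cohorts preserve the repeated-measures structure and ranges", {
  coh <- make_cohort(cohort_config(seed = 42))
  expect_equal(nrow(coh), 21 * 2)
  tab <- table(coh$subject, coh$state)
  expect_true(all(tab == 1))
  expect_true(all(tapply(coh$group, coh$subject,
                         function(g) length(unique(g))) == 1))
  sat_cols <- grep("^sat_", names(coh), value = TRUE)
  expect_true(all(coh[sat_cols] >= 0 & coh[sat_cols] <= 1))
  flow_cols <- grep("^flow_", names(coh), value = TRUE)
  expect_true(all(coh[flow_cols] >= 0))
  # generated circulations are self-consistent by construction
  expect_equal(coh$flow_MPA, coh$flow_DA + coh$flow_LPA + coh$flow_RPA)
  # one-per-subject variables are identical across states
  expect_true(all(tapply(coh$weight_g, coh$subject,
                         function(w) length(unique(w))) == 1))
  expect_error(make_cohort(cohort_config(n_control = 0)), "positive")
})

test_that("disabling the FGR pulmonary effect removes the group difference", {
  # with the effect off, an unpaired t-test on normoxia PBF rejects at the
  # nominal 5% rate across replicate cohorts
  rej <- vapply(1:400, function(s) {
    coh <- make_cohort(cohort_config(seed = s, effect_pbf = FALSE))
    nor <- coh[coh$state == "normoxia", ]
    pbf <- nor$flow_LPA + nor$flow_RPA
    unpaired_t_test(pbf[nor$group == "control"],
                    pbf[nor$group == "FGR"])$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)   # ~3 binomial SDs at 400 reps
})
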