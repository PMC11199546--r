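# End-to-end pipeline ---------------------------------------------------------

#' Pipeline run configuration
#'
#' One master seed governs cohort generation, every phantom and all noise;
#' per-stage seeds are derived deterministically ([derive_seed()]), so a
#' rerun with the same configuration reproduces every table byte-identically.
#'
#' @param seed Master integer seed.
#' @param n_control,n_fgr Subjects per group. The full study design is 12/9;
#'   the demo default (3/3) keeps an imaging run light.
#' @param imaging If `TRUE` (default), vessel flows and saturations are
#'   measured by synthesising and analysing phase-contrast and T2-prepared
#'   phantoms per subject x state x vessel; if `FALSE`, the tabular cohort
#'   values are analysed directly.
#' @param vessel_radius_px Phantom lumen radius (default 10 px).
#' @param pixel_spacing_mm In-plane phantom pixel size (default 1 mm).
#' @param n_phases Cardiac phases per cine series (default 15).
#' @param phase_noise_sd Phantom phase noise, radians.
#' @param background_offset Phantom background phase offset, radians
#'   (removed by the static-tissue correction during measurement).
#' @param t2_snr Signal-to-noise ratio of the T2 phantoms (`noise_sd =
#'   s0 / t2_snr`).
#' @param calib T2 calibration ([t2_calibration()]); defaults are
#'   provisional.
#' @param factors Volumetry conversion factors ([conversion_factors()]);
#'   defaults are provisional.
#' @param central_fraction Oximetry ROI area fraction (default 0.6).
#' @param conservation_tol_pct Conservation tolerance for measured flows,
#'   percent.
#' @param alpha Significance level for pairwise flags.
#' @param write_images Also write one example subject's NIfTI stacks (+
#'   sidecars) under `out_dir/images/`.
#' @param ... Passed to [cohort_config()] (effect toggles, `subject_icc`,
#'   `means`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_control = 3L, n_fgr = 3L,
                            imaging = TRUE, vessel_radius_px = 10L,
                            pixel_spacing_mm = 1.0, n_phases = 15L,
                            phase_noise_sd = 0.01, background_offset = 0.05,
                            t2_snr = 50, calib = t2_calibration(),
                            factors = conversion_factors(),
                            central_fraction = 0.6,
                            conservation_tol_pct = 5, alpha = 0.05,
                            write_images = FALSE, ...) {
  cohort <- cohort_config(n_control = n_control, n_fgr = n_fgr,
                          seed = derive_seed(seed, "cohort"), ...)
  structure(list(seed = as.integer(seed), cohort = cohort,
                 imaging = imaging,
                 vessel_radius_px = as.integer(vessel_radius_px),
                 pixel_spacing_mm = pixel_spacing_mm,
                 n_phases = as.integer(n_phases),
                 phase_noise_sd = phase_noise_sd,
                 background_offset = background_offset, t2_snr = t2_snr,
                 calib = calib, factors = factors,
                 central_fraction = central_fraction,
                 conservation_tol_pct = conservation_tol_pct,
                 alpha = alpha, write_images = write_images),
            class = "pipeline_config")
}

# Cine phantom for one programmed mean flow; waveform is pulsatile with unit
# mean so the programmed mean flow is preserved.
.flow_phantom_for <- function(q_ml_min, venc, cfg, seed) {
  r_cm <- cfg$vessel_radius_px * cfg$pixel_spacing_mm / 10
  area_cm2 <- pi * r_cm^2
  v_peak <- 2 * (q_ml_min / 60) / area_cm2
  k <- seq_len(cfg$n_phases) - 1
  waveform <- 1 + 0.4 * sin(2 * pi * k / cfg$n_phases)
  make_flow_phantom(phantom_spec(
    vessel_radius_px = cfg$vessel_radius_px, peak_velocity = v_peak,
    venc = venc, waveform = waveform, pixel_spacing = cfg$pixel_spacing_mm,
    n_phases = cfg$n_phases, noise_sd_phase = cfg$phase_noise_sd,
    background_offset = cfg$background_offset, seed = seed))
}

# Measure every vessel of one subject x state row from synthetic images.
.measure_row_imaging <- function(row, cfg) {
  vencs <- default_vencs()
  flows <- sats <- list()
  for (v in names(vencs)) {
    q <- row[[paste0("flow_", v)]]
    ph <- .flow_phantom_for(q, vencs[[v]], cfg,
                            derive_seed(cfg$seed,
                                        paste("flow", row$subject, row$state,
                                              v)))
    ph$heart_rate <- row$heart_rate
    flows[[v]] <- measure_flow(ph, vessel = v)$mean_flow
  }
  for (v in .sat_vessels) {
    y <- row[[paste0("sat_", v)]]
    t2 <- so2_to_t2(y, cfg$calib)
    s0 <- 200
    ph <- make_t2_phantom(t2_phantom_spec(
      t2_ms = t2, s0 = s0, noise_sd = s0 / cfg$t2_snr,
      vessel_radius_px = cfg$vessel_radius_px,
      seed = derive_seed(cfg$seed,
                         paste("t2", row$subject, row$state, v))))
    sats[[v]] <- measure_saturation(ph, calib = cfg$calib,
                                    central_fraction = cfg$central_fraction)$y
  }
  list(flows = unlist(flows), sats = unlist(sats))
}

# Volumetry for one subject: label volume sized from the true weights, then
# measured back through the biometry module.
.biometry_for <- function(weight_g, brain_g, factors, voxel_mm = c(2, 2, 2)) {
  vx <- prod(voxel_mm)
  fetal_vox <- max(1L, round(weight_g / factors$fetal_g_per_ml * 1000 / vx))
  brain_vox <- max(0L, round(brain_g / factors$brain_g_per_ml * 1000 / vx))
  brain_vox <- min(brain_vox, fetal_vox)
  side <- ceiling((fetal_vox + 1)^(1 / 3)) + 1
  seg <- make_label_volume(c(side, side, side), fetal_vox, brain_vox,
                           voxel_size_mm = voxel_mm)
  vol <- measure_volumes(seg)
  volumes_to_weights(vol$fetal_ml, vol$brain_ml, factors)
}

#' Statistical analysis of an assembled cohort table
#'
#' Derives the circulation haemodynamics, computes the oxygen-transport
#' panel and runs the mixed repeated-measures ANOVA layer on the repeated
#' (two-state) variables plus unpaired t-tests on the one-state variables
#' (uterine-artery flow, fetal weight, relative brain weight).
#'
#' @param cohort Data frame with `subject`, `group`, `state`, `flow_*`,
#'   `sat_*`, `hb_g_per_l`, `heart_rate`, `weight_g` (and optionally
#'   `brain_weight_g`, `uta_flow`).
#' @param alpha Significance level.
#' @return List: `data` (cohort with derived + oxygen columns), `anova`,
#'   `pairwise`, `t_tests`.
#' @export
analyse_cohort <- function(cohort, alpha = 0.05) {
  data <- compute_oxygen_transport(derive_flows_cohort(cohort))
  rm_vars <- c("flow_UV", "flow_DV", "fo_flow", "pbf", "rvco", "lvco", "cvo",
               "flow_DA", "cca_combined", "flow_SVC", "flow_DAo",
               "lower_trunk_flow", "pct_FO", "pct_CCA", "delta_so2_aao_mpa",
               "fetal_do2", "fetal_do2_per_kg", "fetal_vo2",
               "fetal_vo2_per_kg", "fetal_oef", "cerebral_do2",
               "cerebral_do2_per_kg", "cerebral_vo2", "cerebral_vo2_per_kg",
               "cerebral_oef", "heart_rate")
  rm_vars <- intersect(rm_vars, names(data))
  st <- analyse_variables(data, rm_vars)

  t_rows <- list()
  nor <- data[data$state == "normoxia", ]
  if (nrow(nor) > 0) {
    one_state <- intersect(c("uta_flow", "weight_g", "brain_weight_g"),
                           names(nor))
    for (v in one_state) {
      tt <- unpaired_t_test(nor[[v]][nor$group == "control"],
                            nor[[v]][nor$group == "FGR"])
      t_rows[[v]] <- data.frame(variable = v, t = tt$t, df = tt$df, p = tt$p,
                                stringsAsFactors = FALSE)
    }
    if (all(c("brain_weight_g", "weight_g") %in% names(nor))) {
      rel <- nor$brain_weight_g / nor$weight_g * 100
      tt <- unpaired_t_test(rel[nor$group == "control"],
                            rel[nor$group == "FGR"])
      t_rows[["brain_pct_of_body"]] <-
        data.frame(variable = "brain_pct_of_body", t = tt$t, df = tt$df,
                   p = tt$p, stringsAsFactors = FALSE)
    }
  }
  list(data = data, anova = st$table, pairwise = st$pairwise,
       t_tests = do.call(rbind, c(t_rows, list(make.row.names = FALSE))))
}

#' Check the qualitative direction-of-effect pattern
#'
#' Evaluates whether an analysed cohort reproduces the study's directional
#' findings: a group effect on ductus venosus and foramen ovale flow, the
#' group x state pattern on pulmonary blood flow (reduced in FGR during
#' normoxia only), a state effect on cerebral oxygen delivery and on
#' cerebral oxygen extraction fraction, and no state effect on cerebral
#' oxygen consumption.
#'
#' @param analysis Result of [analyse_cohort()].
#' @param alpha Significance level (default 0.05).
#' @return Named logical vector of the six flags plus `all_pass`.
#' @export
qualitative_pattern <- function(analysis, alpha = 0.05) {
  an <- analysis$anova
  p_of <- function(v, eff) an[[eff]][an$variable == v]
  pw <- analysis$pairwise
  grp_cmp <- grepl("FGR", pw$comparison) & grepl("control", pw$comparison)
  pbf_nor <- pw$p_adj[pw$variable == "pbf" & grp_cmp &
                        grepl("normoxia", pw$comparison)]
  pbf_hyp <- pw$p_adj[pw$variable == "pbf" & grp_cmp &
                        grepl("hypoxia", pw$comparison)]
  flags <- c(
    dv_group = p_of("flow_DV", "p_group") < alpha,
    fo_group = p_of("fo_flow", "p_group") < alpha,
    pbf_pattern = p_of("pbf", "p_interaction") < alpha &&
      pbf_nor < alpha && pbf_hyp >= alpha,
    cerebral_do2_state = p_of("cerebral_do2", "p_state") < alpha,
    cerebral_oef_state = p_of("cerebral_oef", "p_state") < alpha,
    cerebral_vo2_state_null = p_of("cerebral_vo2", "p_state") >= alpha)
  c(flags, all_pass = all(flags))
}

#' Run the full pipeline
#'
#' Stages, in order: cohort simulation; per-vessel flow measurement from
#' phase-contrast phantoms; per-vessel saturation from T2-prepared phantoms;
#' volumetry-based weights; circulation assembly with conservation checks;
#' oxygen transport; statistics. Writes tidy CSV tables and a JSON manifest
#' (seed, configuration hash, versions, per-stage row counts) to `out_dir`.
#' Rerunning with the same configuration reproduces all tables
#' byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all result tables and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  .check(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  truth <- make_cohort(config$cohort)

  measured <- truth
  if (config$imaging) {
    for (i in seq_len(nrow(truth))) {
      m <- .measure_row_imaging(truth[i, ], config)
      for (v in names(m$flows))
        measured[[paste0("flow_", v)]][i] <- m$flows[[v]]
      for (v in names(m$sats))
        measured[[paste0("sat_", v)]][i] <- m$sats[[v]]
    }
  }

  # volumetry once per subject
  subj <- unique(truth[, c("subject", "weight_g", "brain_weight_g")])
  bio <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
    w <- .biometry_for(subj$weight_g[i], subj$brain_weight_g[i],
                       config$factors)
    data.frame(subject = subj$subject[i], fetal_g = w$fetal_g,
               brain_g = w$brain_g, brain_pct_of_body = w$brain_pct_of_body,
               stringsAsFactors = FALSE)
  }))
  measured$weight_g <- bio$fetal_g[match(measured$subject, bio$subject)]
  measured$brain_weight_g <- bio$brain_g[match(measured$subject, bio$subject)]

  analysis <- analyse_cohort(measured, alpha = config$alpha)

  cons <- lapply(seq_len(nrow(analysis$data)), function(i) {
    f <- unlist(analysis$data[i, paste0("flow_", c(.required_flow_vessels))])
    names(f) <- sub("^flow_", "", names(f))
    cc <- check_conservation(f, tol_pct = config$conservation_tol_pct)
    data.frame(subject = analysis$data$subject[i],
               state = analysis$data$state[i],
               mpa_discrepancy = cc$mpa_discrepancy,
               partition_sum_pct = cc$partition_sum_pct, pass = cc$pass,
               stringsAsFactors = FALSE)
  })
  cons <- do.call(rbind, cons)

  pattern <- qualitative_pattern(analysis, alpha = config$alpha)

  if (config$write_images) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    row <- truth[1, ]
    ph <- .flow_phantom_for(row$flow_AAo, default_vencs()[["AAo"]], config,
                            derive_seed(config$seed,
                                        paste("flow", row$subject, row$state,
                                              "AAo")))
    write_cine_nifti(ph, file.path(img_dir, "AAo_mag.nii.gz"),
                     file.path(img_dir, "AAo_phase.nii.gz"))
    t2ph <- make_t2_phantom(t2_phantom_spec(
      t2_ms = so2_to_t2(row$sat_AAo, config$calib), s0 = 200,
      noise_sd = 200 / config$t2_snr,
      vessel_radius_px = config$vessel_radius_px,
      seed = derive_seed(config$seed,
                         paste("t2", row$subject, row$state, "AAo"))))
    write_t2_nifti(t2ph, file.path(img_dir, "AAo_t2prep.nii.gz"))
  }

  wcsv <- function(d, name) {
    utils::write.csv(d, file.path(out_dir, name), row.names = FALSE)
    nrow(d)
  }
  counts <- c(
    cohort_truth = wcsv(truth, "cohort_truth.csv"),
    cohort_measured = wcsv(measured, "cohort_measured.csv"),
    derived_oxygen = wcsv(analysis$data, "derived_oxygen.csv"),
    biometry = wcsv(bio, "biometry.csv"),
    stats_anova = wcsv(analysis$anova, "stats_anova.csv"),
    stats_pairwise = wcsv(analysis$pairwise, "stats_pairwise.csv"),
    stats_t_tests = wcsv(analysis$t_tests, "stats_t_tests.csv"))
  jsonlite::write_json(cons, file.path(out_dir, "conservation.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  cfg_plain <- rapply(unclass(config), function(x)
    if (is.function(x)) NULL else x, how = "replace")
  cfg_json <- jsonlite::toJSON(cfg_plain, auto_unbox = TRUE, digits = NA,
                               null = "null", force = TRUE)
  tf <- tempfile(fileext = ".json")
  writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf))
  unlink(tf)
  provisional <- list(
    t2_calibration = "not ground truth: laboratory calibration required",
    conversion_factors = "not ground truth: literature values required",
    vessel_flow_means = "not ground truth: plausible defaults, editable")
  manifest <- list(seed = config$seed, config_hash = cfg_hash,
                   package_version = as.character(
                     utils::packageVersion("fetalox")),
                   r_version = R.version.string,
                   provisional_constants = provisional,
                   rows = as.list(counts),
                   qualitative_pattern = as.list(pattern),
                   conservation_all_pass = all(cons$pass))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(truth = truth, measured = measured, analysis = analysis,
                 biometry = bio, conservation = cons, pattern = pattern,
                 manifest = manifest))
}
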