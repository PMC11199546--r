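# Virtual cohort generator ----------------------------------------------------
#
# The cohort emulates the study design: n = 12 control and n = 9
# growth-restricted (FGR) fetal sheep, each measured in a normoxia and an
# acute-hypoxia state (repeated measures). Arterial saturation (AAo),
# haemoglobin and heart rate defaults are anchored to published group x state
# summary values for this design; per-vessel flow means and SDs are not
# published anywhere and the defaults below are provisional, physiologically plausible
# values for ~118-day fetal sheep (see the methods vignette). Edit via the
# `means` override of cohort_config().

.flow_vessels <- c("UV", "DV", "AAo", "DA", "DAo", "SVC",
                   "LPA", "RPA", "CCA_left", "CCA_right")
.sat_vessels <- c("UV", "DV", "AAo", "MPA", "DA", "DAo", "SVC")

#' Vessel velocity-encoding (VENC) defaults, cm/s
#'
#' The per-vessel VENC values used for the phase-contrast acquisitions:
#' AAo, MPA, DAo and DA at 150; SVC, CCA and DV at 100; LPA/RPA at 80;
#' UV at 50 cm/s.
#' @return Named numeric vector, cm/s.
#' @export
default_vencs <- function() {
  c(AAo = 150, MPA = 150, DAo = 150, DA = 150, SVC = 100,
    CCA_left = 100, CCA_right = 100, DV = 100, LPA = 80, RPA = 80, UV = 50)
}

# Default group x state parameter table (long format).
.default_params <- function(effect_dv_fo = TRUE, effect_pbf = TRUE,
                            effect_hypoxia_sat = TRUE) {
  grid <- expand.grid(group = c("control", "FGR"),
                      state = c("normoxia", "hypoxia"),
                      stringsAsFactors = FALSE)
  rows <- list()
  add <- function(variable, means, sds, provisional = TRUE) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, group = grid$group, state = grid$state,
      mean = means, sd = sds, provisional = provisional,
      stringsAsFactors = FALSE)
  }
  # order of means/sds: control-normoxia, FGR-normoxia, control-hypoxia, FGR-hypoxia

  # Flows, mL/min (provisional: no published per-vessel values exist)
  fgr_dv <- if (effect_dv_fo) 100 else 70
  fgr_aao <- if (effect_dv_fo) c(240, 260) else c(220, 220)  # normoxia, hypoxia
  fgr_pa_nor <- if (effect_pbf) 18 else 35                   # per lung artery
  add("flow_UV",  c(250, 230, 250, 230), rep(40, 4))
  add("flow_DV",  c(70, fgr_dv, 70, fgr_dv), rep(12, 4))
  add("flow_AAo", c(220, fgr_aao[1], 220, fgr_aao[2]), rep(30, 4))
  add("flow_DA",  c(250, 230, 250, 230), rep(35, 4))
  add("flow_DAo", c(330, 310, 330, 310), rep(45, 4))
  add("flow_SVC", c(130, 120, 130, 120), rep(20, 4))
  add("flow_LPA", c(35, fgr_pa_nor, 35, 35), rep(6, 4))
  add("flow_RPA", c(35, fgr_pa_nor, 35, 35), rep(6, 4))
  add("flow_CCA_left",  c(30, 28, 30, 28), rep(5, 4))
  add("flow_CCA_right", c(30, 28, 30, 28), rep(5, 4))

  # Saturations, fraction. AAo anchored to the published arterial SaO2
  # (58.5 +- 7.5 control / 47.4 +- 7.3 FGR in normoxia; 29 +- 7.6 /
  # 27.4 +- 6.1 in hypoxia); other vessels provisional, set so that the
  # AAo-SVC difference is state-invariant (cerebral VO2 maintained by
  # increased extraction) and the AAo-MPA gap widens under hypoxia.
  hyp <- effect_hypoxia_sat
  sat <- function(nor_c, nor_f, hyp_c, hyp_f)
    if (hyp) c(nor_c, nor_f, hyp_c, hyp_f) else c(nor_c, nor_f, nor_c, nor_f)
  add("sat_AAo", sat(0.585, 0.474, 0.290, 0.274),
      c(0.075, 0.073, 0.076, 0.061), provisional = FALSE)
  add("sat_UV",  sat(0.800, 0.700, 0.520, 0.480), rep(0.05, 4))
  add("sat_DV",  sat(0.780, 0.680, 0.500, 0.460), rep(0.05, 4))
  add("sat_MPA", sat(0.505, 0.394, 0.170, 0.154), rep(0.05, 4))
  add("sat_DA",  sat(0.500, 0.390, 0.165, 0.150), rep(0.05, 4))
  add("sat_DAo", sat(0.530, 0.420, 0.220, 0.200), rep(0.05, 4))
  add("sat_SVC", sat(0.350, 0.239, 0.055, 0.039), rep(0.05, 4))

  # Haemoglobin g/L and heart rate bpm, published group x state values.
  add("hb_g_per_l", c(98, 92, 98, 100), c(9, 10, 11, 10), provisional = FALSE)
  add("heart_rate", c(140, 142, 146, 148), c(10, 16, 21, 19),
      provisional = FALSE)

  # One-per-subject variables (replicated across states): weights (g) and
  # maternal uterine-artery flow (mL/min), all provisional.
  add("weight_g", c(1250, 820, 1250, 820), c(140, 130, 140, 130))
  add("brain_weight_g", c(45, 42, 45, 42), c(5, 5, 5, 5))
  add("uta_flow", c(900, 550, 900, 550), c(200, 150, 200, 150))

  do.call(rbind, rows)
}

#' Configuration for the virtual cohort generator
#'
#' @param n_control,n_fgr Subjects per group (defaults 12 and 9, the study
#'   design).
#' @param effect_dv_fo If `TRUE` (default), FGR fetuses have raised ductus
#'   venosus flow and raised ascending-aortic flow (hence raised foramen
#'   ovale flow) in both states.
#' @param effect_pbf If `TRUE` (default), FGR fetuses have reduced pulmonary
#'   blood flow in the normoxia state only (group x state interaction).
#' @param effect_hypoxia_sat If `TRUE` (default), all vessel saturations fall
#'   in the acute-hypoxia state.
#' @param subject_icc Fraction of each variable's variance attributed to a
#'   subject-level random intercept shared by the two states (repeated-
#'   measures correlation). Default 0.5.
#' @param means Optional override: a data frame with columns
#'   `variable, group, state, mean, sd` replacing matching rows of the
#'   default table.
#' @param seed Integer master seed.
#' @return An object of class `cohort_config` with the resolved parameter
#'   table in `$params`.
#' @export
cohort_config <- function(n_control = 12L, n_fgr = 9L,
                          effect_dv_fo = TRUE, effect_pbf = TRUE,
                          effect_hypoxia_sat = TRUE,
                          subject_icc = 0.5, means = NULL, seed = 1L) {
  .check(n_control >= 1 && n_fgr >= 1, "group sizes must be positive")
  .check(subject_icc >= 0 && subject_icc <= 1, "subject_icc must be in [0,1]")
  params <- .default_params(effect_dv_fo, effect_pbf, effect_hypoxia_sat)
  if (!is.null(means)) {
    .check(all(c("variable", "group", "state", "mean", "sd") %in% names(means)),
           "means override needs columns variable, group, state, mean, sd")
    key <- function(d) paste(d$variable, d$group, d$state)
    idx <- match(key(means), key(params))
    .check(!anyNA(idx), "means override refers to unknown variable/group/state")
    params$mean[idx] <- means$mean
    params$sd[idx] <- means$sd
  }
  .check(all(params$sd >= 0), "all SDs must be >= 0")
  sat_rows <- grepl("^sat_", params$variable)
  .check(all(params$mean[sat_rows] >= 0 & params$mean[sat_rows] <= 1),
         "saturation means must lie in [0,1]")
  structure(list(n_control = as.integer(n_control), n_fgr = as.integer(n_fgr),
                 subject_icc = subject_icc, params = params,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# variables measured once per subject, replicated across the two states
.once_vars <- c("weight_g", "brain_weight_g", "uta_flow")

# physical range per variable
.var_range <- function(v) {
  if (grepl("^sat_", v)) c(0, 1) else c(0, Inf)
}

#' Generate a virtual cohort
#'
#' Draws every variable from its configured group x state normal
#' distribution with a subject-level random intercept (so the two states of
#' one subject are positively correlated), truncating to physical ranges by
#' rejection sampling (flows >= 0, saturations in [0,1]). The main pulmonary
#' artery flow is always derived as `MPA = DA + LPA + RPA`, so generated
#' circulations are self-consistent, and the programmed foramen-ovale flow
#' `AAo - (LPA + RPA)` is recorded in `fo_programmed`.
#'
#' @param config A [cohort_config()].
#' @return A data frame, one row per subject x state, with columns `subject`,
#'   `group`, `state`, every configured variable, `flow_MPA` and
#'   `fo_programmed`.
#' @export
make_cohort <- function(config) {
  .check(inherits(config, "cohort_config"), "config must be a cohort_config")
  set.seed(derive_seed(config$seed, "cohort"))
  p <- config$params
  vars <- unique(p$variable)
  icc <- config$subject_icc
  subjects <- data.frame(
    subject = sprintf("S%02d", seq_len(config$n_control + config$n_fgr)),
    group = rep(c("control", "FGR"), c(config$n_control, config$n_fgr)),
    stringsAsFactors = FALSE)
  states <- c("normoxia", "hypoxia")

  out <- merge(subjects,
               data.frame(state = states, stringsAsFactors = FALSE))
  out <- out[order(match(out$subject, subjects$subject),
                   match(out$state, states)), ]
  rownames(out) <- NULL

  draw_pair <- function(mu, sdv, rng) {
    # one subject, both states: shared intercept + state noise, truncated by
    # rejection on the whole pair (avoids point masses at the bounds)
    if (all(sdv == 0)) return(mu)
    for (i in 1:10000) {
      u <- stats::rnorm(1)
      e <- stats::rnorm(2)
      x <- mu + sdv * (sqrt(icc) * u + sqrt(1 - icc) * e)
      if (all(x >= rng[1] & x <= rng[2])) return(x)
    }
    stop("rejection sampling failed: configured mean/sd incompatible with ",
         "the physical range", call. = FALSE)
  }

  for (v in vars) {
    rng <- .var_range(v)
    vals <- numeric(nrow(out))
    for (s in seq_len(nrow(subjects))) {
      g <- subjects$group[s]
      pm <- p[p$variable == v & p$group == g, ]
      pm <- pm[match(states, pm$state), ]
      if (v %in% .once_vars) {
        x1 <- draw_pair(rep(pm$mean[1], 2), rep(pm$sd[1], 2), rng)[1]
        x <- rep(x1, 2)
      } else {
        x <- draw_pair(pm$mean, pm$sd, rng)
      }
      vals[out$subject == subjects$subject[s]] <- x
    }
    out[[v]] <- vals
  }
  out$flow_MPA <- out$flow_DA + out$flow_LPA + out$flow_RPA
  out$fo_programmed <- out$flow_AAo - (out$flow_LPA + out$flow_RPA)
  out
}
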