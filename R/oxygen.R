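# Fick-principle oxygen transport ---------------------------------------------
#
# Unit regime, fixed throughout: haemoglobin in g/L, flows in mL/min, blood
# oxygen content in mL O2 per L blood. Delivery/consumption in mL O2/min
# therefore needs a /1000 factor (mL/min of blood x mL O2/L of blood). The
# binding capacity of 1.36 mL O2 (at 1 atmosphere) per gram of haemoglobin
# is used; dissolved oxygen is neglected.

O2_PER_G_HB <- 1.36

#' Oxygen content of blood
#'
#' `1.36 * [Hb] * Y`, in mL O2 per litre of blood.
#'
#' @param hb_g_per_l Haemoglobin concentration, g/L (> 0).
#' @param y Oxygen saturation fraction in [0, 1].
#' @return mL O2 / L blood (vectorised).
#' @export
o2_content <- function(hb_g_per_l, y) {
  .check(all(hb_g_per_l > 0), "hb must be > 0")
  .check(all(y >= 0 & y <= 1), "y must lie in [0, 1]")
  O2_PER_G_HB * hb_g_per_l * y
}

#' Fetal oxygen delivery
#'
#' `DO2 = 1.36 * Hb * Y_UV * Q_UV / 1000`: oxygen carried to the fetus by
#' the umbilical venous return.
#'
#' @param hb_g_per_l Haemoglobin, g/L.
#' @param y_uv Umbilical-vein saturation fraction.
#' @param q_uv Umbilical-vein flow, mL/min (>= 0).
#' @return mL O2 / min (vectorised).
#' @export
fetal_do2 <- function(hb_g_per_l, y_uv, q_uv) {
  .check(all(q_uv >= 0), "q_uv must be >= 0")
  o2_content(hb_g_per_l, y_uv) * q_uv / 1000
}

#' Cerebral oxygen delivery
#'
#' `DO2 = 1.36 * Hb * Y_AAo * Q_CCa / 1000`, where `Q_CCa` is the combined
#' flow of the left and right carotid arteries.
#'
#' @param hb_g_per_l Haemoglobin, g/L.
#' @param y_aao Ascending-aorta saturation fraction.
#' @param q_cca Combined carotid flow, mL/min (>= 0).
#' @return mL O2 / min (vectorised).
#' @export
cerebral_do2 <- function(hb_g_per_l, y_aao, q_cca) {
  .check(all(q_cca >= 0), "q_cca must be >= 0")
  o2_content(hb_g_per_l, y_aao) * q_cca / 1000
}

#' Fetal oxygen consumption
#'
#' `VO2 = 1.36 * Hb * (Y_UV - Y_DAo) * Q_UV / 1000` (Fick principle across
#' the umbilical circulation). A negative arteriovenous difference is
#' returned as-is with attribute `flagged = TRUE` rather than clipped: it
#' indicates inconsistent oximetry worth surfacing.
#'
#' @param hb_g_per_l Haemoglobin, g/L.
#' @param y_uv,y_dao Umbilical-vein and descending-aorta saturations.
#' @param q_uv Umbilical-vein flow, mL/min.
#' @return mL O2 / min (vectorised), attribute `flagged` marks negative
#'   differences.
#' @export
fetal_vo2 <- function(hb_g_per_l, y_uv, y_dao, q_uv) {
  .check(all(q_uv >= 0), "q_uv must be >= 0")
  .check(all(y_dao >= 0 & y_dao <= 1), "y_dao must lie in [0, 1]")
  .check(all(y_uv >= 0 & y_uv <= 1), "y_uv must lie in [0, 1]")
  .check(all(hb_g_per_l > 0), "hb must be > 0")
  out <- O2_PER_G_HB * hb_g_per_l * (y_uv - y_dao) * q_uv / 1000
  attr(out, "flagged") <- y_uv < y_dao
  out
}

#' Cerebral oxygen consumption
#'
#' `VO2 = 1.36 * Hb * (Y_AAo - Y_SVC) * Q_CCa / 1000` (Fick principle across
#' the cerebral circulation, SVC return).
#'
#' @param hb_g_per_l Haemoglobin, g/L.
#' @param y_aao,y_svc Ascending-aorta and superior-vena-cava saturations.
#' @param q_cca Combined carotid flow, mL/min.
#' @return mL O2 / min (vectorised), attribute `flagged` marks negative
#'   differences.
#' @export
cerebral_vo2 <- function(hb_g_per_l, y_aao, y_svc, q_cca) {
  .check(all(q_cca >= 0), "q_cca must be >= 0")
  .check(all(y_aao >= 0 & y_aao <= 1), "y_aao must lie in [0, 1]")
  .check(all(y_svc >= 0 & y_svc <= 1), "y_svc must lie in [0, 1]")
  .check(all(hb_g_per_l > 0), "hb must be > 0")
  out <- O2_PER_G_HB * hb_g_per_l * (y_aao - y_svc) * q_cca / 1000
  attr(out, "flagged") <- y_aao < y_svc
  out
}

#' Oxygen extraction fraction
#'
#' `(Y_in - Y_out) / Y_in` over the same vessel pairs the consumption
#' equations use (fetal: UV vs DAo; cerebral: AAo vs SVC). Values outside
#' [0, 1] are flagged, not clipped.
#'
#' @param y_in Arterial-side saturation (> 0).
#' @param y_out Venous-side saturation.
#' @return Fraction (vectorised), attribute `flagged` marks values outside
#'   [0, 1].
#' @export
extraction_fraction <- function(y_in, y_out) {
  .check(all(y_in > 0), "y_in must be > 0")
  out <- (y_in - y_out) / y_in
  attr(out, "flagged") <- out < 0 | out > 1
  out
}

#' Normalise an absolute rate to body weight
#'
#' @param value Absolute quantity, e.g. mL O2/min.
#' @param weight_g Body weight, g (> 0).
#' @return Per-kg quantity, e.g. mL O2/min/kg (vectorised).
#' @export
normalise_per_kg <- function(value, weight_g) {
  .check(all(weight_g > 0), "weight_g must be > 0")
  value / (weight_g / 1000)
}

#' Compute the oxygen-transport panel for a cohort table
#'
#' Adds fetal and cerebral oxygen delivery, consumption (absolute and per
#' kg) and extraction fractions to a cohort table that already carries
#' derived haemodynamics ([derive_flows_cohort()]), saturations, haemoglobin
#' and weights.
#'
#' @param cohort Data frame with columns `flow_UV`, `cca_combined`,
#'   `sat_UV`, `sat_DAo`, `sat_AAo`, `sat_SVC`, `hb_g_per_l`, `weight_g`.
#' @return The input with columns `fetal_do2`, `cerebral_do2`, `fetal_vo2`,
#'   `cerebral_vo2`, their `_per_kg` versions, `fetal_oef`, `cerebral_oef`.
#' @export
compute_oxygen_transport <- function(cohort) {
  need <- c("flow_UV", "cca_combined", "sat_UV", "sat_DAo", "sat_AAo",
            "sat_SVC", "hb_g_per_l", "weight_g")
  missing <- setdiff(need, names(cohort))
  .check(length(missing) == 0,
         paste("missing columns:", paste(missing, collapse = ", ")))
  out <- cohort
  out$fetal_do2 <- fetal_do2(cohort$hb_g_per_l, cohort$sat_UV, cohort$flow_UV)
  out$cerebral_do2 <- cerebral_do2(cohort$hb_g_per_l, cohort$sat_AAo,
                                   cohort$cca_combined)
  out$fetal_vo2 <- as.numeric(
    fetal_vo2(cohort$hb_g_per_l, cohort$sat_UV, cohort$sat_DAo,
              cohort$flow_UV))
  out$cerebral_vo2 <- as.numeric(
    cerebral_vo2(cohort$hb_g_per_l, cohort$sat_AAo, cohort$sat_SVC,
                 cohort$cca_combined))
  for (v in c("fetal_do2", "cerebral_do2", "fetal_vo2", "cerebral_vo2"))
    out[[paste0(v, "_per_kg")]] <- normalise_per_kg(out[[v]], cohort$weight_g)
  out$fetal_oef <- as.numeric(extraction_fraction(cohort$sat_UV,
                                                  cohort$sat_DAo))
  out$cerebral_oef <- as.numeric(extraction_fraction(cohort$sat_AAo,
                                                     cohort$sat_SVC))
  out
}
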