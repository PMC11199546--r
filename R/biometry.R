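# MRI volumetry: volumes and weights ------------------------------------------

#' Measure fetal and brain volumes from a label map
#'
#' Label convention: 0 background, 1 fetal body, 2 brain; the brain lies
#' inside the fetal body, so the fetal volume counts labels 1 and 2.
#'
#' @param seg A `volume_segmentation` (see [make_label_volume()]) or a list
#'   with `label_map` and `voxel_volume_mm3`.
#' @return List: `fetal_ml`, `brain_ml`.
#' @export
measure_volumes <- function(seg) {
  lab <- seg$label_map
  .check(!is.null(lab) && !is.null(seg$voxel_volume_mm3),
         "seg must carry label_map and voxel_volume_mm3")
  .check(all(lab %in% c(0L, 1L, 2L)), "unknown labels in label map")
  vx <- seg$voxel_volume_mm3
  .check(vx > 0, "voxel volume must be > 0")
  list(fetal_ml = sum(lab == 1L | lab == 2L) * vx / 1000,
       brain_ml = sum(lab == 2L) * vx / 1000)
}

#' Tissue-specific volume-to-weight conversion factors
#'
#' The factors the volumetry literature supplies for converting segmented
#' fetal and brain volumes to weights are laboratory-specific and not
#' published in reusable numeric form; the defaults (soft-tissue densities of ~1.03-1.04 g/mL) are
#' provisional and must be treated as configuration.
#'
#' @param fetal_g_per_ml,brain_g_per_ml Densities, g/mL (> 0).
#' @return An object of class `conversion_factors`.
#' @export
conversion_factors <- function(fetal_g_per_ml = 1.03, brain_g_per_ml = 1.04) {
  .check(fetal_g_per_ml > 0 && brain_g_per_ml > 0, "factors must be > 0")
  structure(list(fetal_g_per_ml = fetal_g_per_ml,
                 brain_g_per_ml = brain_g_per_ml, provisional = TRUE),
            class = "conversion_factors")
}

#' Convert volumes to weights
#'
#' @param fetal_ml,brain_ml Volumes in mL (`brain_ml <= fetal_ml`).
#' @param factors A [conversion_factors()].
#' @return List: `fetal_g`, `brain_g`, `brain_pct_of_body` (NA when both
#'   weights are zero).
#' @export
volumes_to_weights <- function(fetal_ml, brain_ml,
                               factors = conversion_factors()) {
  .check(inherits(factors, "conversion_factors"),
         "factors must be conversion_factors")
  .check(fetal_ml >= 0 && brain_ml >= 0, "volumes must be >= 0")
  fetal_g <- fetal_ml * factors$fetal_g_per_ml
  brain_g <- brain_ml * factors$brain_g_per_ml
  if (fetal_g == 0 && brain_g > 0)
    stop("brain weight without body weight is inconsistent", call. = FALSE)
  pct <- if (fetal_g == 0) NA_real_ else brain_g / fetal_g * 100
  list(fetal_g = fetal_g, brain_g = brain_g, brain_pct_of_body = pct)
}
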