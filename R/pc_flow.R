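# Cine phase-contrast flow quantification -------------------------------------

#' Convert phase images to through-plane velocity
#'
#' Standard PC-MRI linear mapping: a phase of \eqn{\pi} corresponds to the
#' velocity-encoding limit, so \eqn{v = (\phi/\pi) \times VENC} elementwise.
#'
#' @param x A `cine_series` (its `phase` stack and `venc` are used) or a
#'   numeric array/matrix of phase values in radians.
#' @param venc Velocity-encoding limit, cm/s; taken from the series when `x`
#'   is a `cine_series`.
#' @return Velocity in cm/s, same shape as the input phase.
#' @export
phase_to_velocity <- function(x, venc = NULL) {
  if (inherits(x, "cine_series")) {
    venc <- venc %||% x$venc
    x <- x$phase
  }
  .check(is.numeric(venc) && length(venc) == 1 && venc > 0, "venc must be > 0")
  x / pi * venc
}

#' Correct velocity aliasing (phase wraps)
#'
#' Any pixel whose velocity sign opposes the ROI-median sign and whose
#' magnitude exceeds `venc/2` is shifted by `2 * venc` toward the median
#' sign. Idempotent on alias-free data. Aliasing correction is opt-in in the
#' pipeline: the acquisition VENCs are chosen to avoid wraps.
#'
#' @param velocity Velocity stack (`n_phases x rows x cols`) or matrix, cm/s.
#' @param venc Velocity-encoding limit, cm/s.
#' @param roi Optional logical matrix restricting the median-sign estimate
#'   (default: all pixels). Correction itself is applied everywhere.
#' @return Corrected velocity, same shape.
#' @export
unwrap_velocity <- function(velocity, venc, roi = NULL) {
  .check(venc > 0, "venc must be > 0")
  fix_slice <- function(v) {
    ref <- if (is.null(roi)) v else v[roi]
    if (length(ref) == 0) return(v)
    s <- sign(stats::median(ref))
    if (s == 0) return(v)
    wrap <- sign(v) == -s & abs(v) > venc / 2
    v[wrap] <- v[wrap] + 2 * venc * s
    v
  }
  if (is.matrix(velocity) || is.null(dim(velocity))) return(fix_slice(velocity))
  for (k in seq_len(dim(velocity)[1]))
    velocity[k, , ] <- fix_slice(velocity[k, , ])
  velocity
}

#' Remove a static-tissue background phase offset
#'
#' Subtracts, per cardiac phase, the mean velocity over a static-tissue mask
#' from every pixel. Idempotent (a second application subtracts ~0).
#'
#' @param velocity Velocity stack (`n_phases x rows x cols`) or matrix, cm/s.
#' @param static_mask Logical matrix marking static tissue; must be
#'   non-empty.
#' @return Offset-corrected velocity, same shape.
#' @export
correct_background_offset <- function(velocity, static_mask) {
  .check(is.logical(static_mask) || all(static_mask %in% c(0, 1)),
         "static_mask must be logical")
  static_mask <- static_mask > 0
  .check(any(static_mask),
         "static_mask is empty: no static tissue reference available")
  if (is.matrix(velocity)) {
    .check(all(dim(velocity) == dim(static_mask)), "mask/image shape mismatch")
    return(velocity - mean(velocity[static_mask]))
  }
  .check(all(dim(velocity)[2:3] == dim(static_mask)),
         "mask/image shape mismatch")
  for (k in seq_len(dim(velocity)[1]))
    velocity[k, , ] <- velocity[k, , ] - mean(velocity[k, , ][static_mask])
  velocity
}

#' Integrate velocity over a lumen ROI to volumetric flow
#'
#' Per-phase flow is the sum of in-ROI velocities times the pixel area,
#' converted to mL/min (1 cm/s over 1 cm^2 = 60 mL/min); the reported mean
#' flow is the arithmetic mean of the per-phase waveform. Positive flow
#' follows the through-plane reference direction.
#'
#' @param velocity Velocity stack (`n_phases x rows x cols`) or a single
#'   matrix, cm/s.
#' @param roi Logical lumen mask, same in-plane shape; non-empty.
#' @param pixel_spacing Pixel edge, mm.
#' @param heart_rate Heart rate, bpm (metadata; recorded in the result).
#' @param vessel Vessel name (metadata).
#' @return A `flow_measurement` list: `vessel`, `mean_flow` (mL/min),
#'   `waveform` (per-phase mL/min), `n_pixels`, `heart_rate`.
#' @export
integrate_flow <- function(velocity, roi, pixel_spacing,
                           heart_rate = NA_real_, vessel = "") {
  .check(pixel_spacing > 0, "pixel_spacing must be > 0")
  roi <- roi > 0
  .check(any(roi), "ROI is empty")
  if (is.matrix(velocity)) velocity <- array(velocity, c(1, dim(velocity)))
  .check(length(dim(velocity)) == 3, "velocity must be a matrix or 3-D stack")
  .check(all(dim(velocity)[2:3] == dim(roi)),
         "ROI does not match the image grid")
  area_cm2 <- (pixel_spacing / 10)^2
  waveform <- vapply(seq_len(dim(velocity)[1]),
                     function(k) sum(velocity[k, , ][roi]) * area_cm2 * 60,
                     numeric(1))
  structure(list(vessel = vessel, mean_flow = mean(waveform),
                 waveform = waveform, n_pixels = sum(roi),
                 heart_rate = heart_rate),
            class = "flow_measurement")
}

#' Temporal resolution of a cine acquisition
#'
#' @param heart_rate Heart rate, bpm (> 0).
#' @param n_phases Number of acquired cardiac phases (>= 1). With 15 phases
#'   at a fetal heart rate of 140 bpm this is ~28.6 ms.
#' @return Milliseconds per cardiac phase.
#' @export
temporal_resolution <- function(heart_rate, n_phases) {
  .check(is.numeric(heart_rate) && heart_rate > 0, "heart_rate must be > 0")
  .check(is.numeric(n_phases) && n_phases >= 1, "n_phases must be >= 1")
  (60000 / heart_rate) / n_phases
}

#' Automatic lumen ROI from the magnitude images
#'
#' Otsu threshold on the time-averaged magnitude (optionally restricted to a
#' seed box), then the largest connected component above threshold.
#'
#' @param series A `cine_series`.
#' @param seed_box Optional `c(row_min, row_max, col_min, col_max)` window;
#'   default: whole image.
#' @return Logical lumen mask.
#' @export
auto_roi <- function(series, seed_box = NULL) {
  .check(inherits(series, "cine_series"), "series must be a cine_series")
  avg <- apply(series$magnitude, c(2, 3), mean)
  win <- matrix(TRUE, nrow(avg), ncol(avg))
  if (!is.null(seed_box)) {
    .check(length(seed_box) == 4, "seed_box must be c(r1, r2, c1, c2)")
    win[] <- FALSE
    win[seed_box[1]:seed_box[2], seed_box[3]:seed_box[4]] <- TRUE
  }
  sub <- avg
  sub[!win] <- min(avg)
  rng <- range(sub)
  .check(diff(rng) > 0, "magnitude image is constant; cannot threshold")
  norm <- (sub - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- norm > thr & win
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) stop("no lumen found above threshold", call. = FALSE)
  counts <- tabulate(lab[lab > 0])
  lab == which.max(counts)
}

#' Measure vessel flow from a cine series
#'
#' Convenience wrapper chaining phase-to-velocity conversion, optional
#' aliasing correction, optional static-tissue background-offset correction
#' and ROI flow integration.
#'
#' @param series A `cine_series`.
#' @param roi Logical lumen mask; default: the series' `lumen` mask if
#'   present, else [auto_roi()].
#' @param correct_offset Subtract the static-mask mean phase per frame
#'   (default `TRUE` when the series carries a `static_mask`).
#' @param unwrap Apply aliasing correction (default `FALSE`).
#' @param vessel Vessel name recorded in the result.
#' @return A `flow_measurement`.
#' @export
measure_flow <- function(series, roi = NULL,
                         correct_offset = !is.null(series$static_mask),
                         unwrap = FALSE, vessel = "") {
  .check(inherits(series, "cine_series"), "series must be a cine_series")
  roi <- roi %||% series$lumen %||% auto_roi(series)
  v <- phase_to_velocity(series)
  if (unwrap) v <- unwrap_velocity(v, series$venc, roi)
  if (correct_offset) v <- correct_background_offset(v, series$static_mask)
  integrate_flow(v, roi, series$pixel_spacing,
                 heart_rate = series$heart_rate, vessel = vessel)
}
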