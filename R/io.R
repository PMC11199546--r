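# NIfTI + sidecar I/O ---------------------------------------------------------
#
# Image stacks travel as NIfTI (.nii.gz) with acquisition metadata (VENC,
# spacing, heart rate, preparation times, seed) in a sidecar JSON next to the
# image; tables travel as tidy CSV. Stacks are stored x-fastest with the
# cardiac-phase / prep-time index as the third dimension.

.stack_to_nifti <- function(stack, pixel_spacing, slice_thickness = 1) {
  # internal order is (frame, row, col); store as (row, col, frame)
  img <- RNifti::asNifti(aperm(stack, c(2, 3, 1)))
  RNifti::pixdim(img) <- c(pixel_spacing, pixel_spacing, slice_thickness)
  img
}

.nifti_to_stack <- function(img) {
  arr <- as.array(img)
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 1))
  aperm(arr, c(3, 1, 2))
}

#' Write a cine phase-contrast series as NIfTI + sidecar JSON
#'
#' @param series A `cine_series`.
#' @param mag_path,phase_path Output paths (`.nii.gz`).
#' @param sidecar_path Output JSON path; defaults to `mag_path` with a
#'   `.json` extension.
#' @return Invisibly, the sidecar path.
#' @export
write_cine_nifti <- function(series, mag_path, phase_path,
                             sidecar_path = NULL) {
  .check(inherits(series, "cine_series"), "series must be a cine_series")
  sidecar_path <- sidecar_path %||%
    paste0(sub("\\.nii(\\.gz)?$", "", mag_path), ".json")
  RNifti::writeNifti(.stack_to_nifti(series$magnitude, series$pixel_spacing,
                                     series$slice_thickness), mag_path)
  RNifti::writeNifti(.stack_to_nifti(series$phase, series$pixel_spacing,
                                     series$slice_thickness), phase_path)
  meta <- list(venc_cm_s = series$venc, pixel_spacing_mm = series$pixel_spacing,
               slice_thickness_mm = series$slice_thickness,
               n_phases = series$n_phases, heart_rate_bpm = series$heart_rate,
               seed = series$seed)
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path)
}

#' Read a cine phase-contrast series from NIfTI + sidecar JSON
#'
#' @param mag_path,phase_path Input `.nii.gz` paths.
#' @param sidecar_path JSON path; defaults next to `mag_path`.
#' @return A `cine_series`.
#' @export
read_cine_nifti <- function(mag_path, phase_path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||%
    paste0(sub("\\.nii(\\.gz)?$", "", mag_path), ".json")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  mag <- .nifti_to_stack(RNifti::readNifti(mag_path))
  phs <- .nifti_to_stack(RNifti::readNifti(phase_path))
  structure(list(magnitude = mag, phase = phs, venc = meta$venc_cm_s,
                 pixel_spacing = meta$pixel_spacing_mm,
                 slice_thickness = meta$slice_thickness_mm,
                 n_phases = dim(phs)[1],
                 heart_rate = meta$heart_rate_bpm %||% NA_real_,
                 lumen = NULL, static_mask = NULL,
                 seed = meta$seed %||% NA_integer_),
            class = "cine_series")
}

#' Write a T2-prepared series as NIfTI + sidecar JSON
#'
#' @param series A `t2_series`.
#' @param path Output `.nii.gz` path.
#' @param sidecar_path JSON path; defaults next to `path`.
#' @param pixel_spacing In-plane spacing recorded in the header, mm.
#' @return Invisibly, the sidecar path.
#' @export
write_t2_nifti <- function(series, path, sidecar_path = NULL,
                           pixel_spacing = 1.3) {
  .check(inherits(series, "t2_series"), "series must be a t2_series")
  sidecar_path <- sidecar_path %||%
    paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  RNifti::writeNifti(.stack_to_nifti(series$images, pixel_spacing), path)
  jsonlite::write_json(list(prep_times_ms = series$prep_times_ms,
                            seed = series$seed),
                       sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path)
}

#' Read a T2-prepared series from NIfTI + sidecar JSON
#'
#' @param path Input `.nii.gz` path.
#' @param sidecar_path JSON path; defaults next to `path`.
#' @return A `t2_series`.
#' @export
read_t2_nifti <- function(path, sidecar_path = NULL) {
  sidecar_path <- sidecar_path %||%
    paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  img <- .nifti_to_stack(RNifti::readNifti(path))
  .check(dim(img)[1] == length(meta$prep_times_ms),
         "one image per preparation time required")
  structure(list(images = img, prep_times_ms = meta$prep_times_ms,
                 lumen = NULL, seed = meta$seed %||% NA_integer_),
            class = "t2_series")
}

#' Write a label volume as NIfTI
#'
#' @param seg A `volume_segmentation`.
#' @param path Output `.nii.gz` path.
#' @return Invisibly, `path`.
#' @export
write_label_nifti <- function(seg, path) {
  img <- RNifti::asNifti(seg$label_map)
  RNifti::pixdim(img) <- seg$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' @param path Input `.nii.gz` path.
#' @return A `volume_segmentation` (spacing from the header).
#' @export
read_label_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  structure(list(label_map = array(as.integer(round(as.array(img))),
                                   dim = dim(img)),
                 spacing_mm = sp, voxel_volume_mm3 = prod(sp)),
            class = "volume_segmentation")
}
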