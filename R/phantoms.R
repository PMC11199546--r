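#' Specification for a cine phase-contrast flow phantom
#'
#' Describes a single-vessel phantom: a circular lumen with a fully developed
#' (parabolic) laminar velocity profile, imaged as a magnitude + phase pair per
#' cardiac phase. The phase image encodes through-plane velocity as
#' \eqn{\phi = \pi v / VENC}, wrapped to \eqn{(-\pi, \pi]}.
#'
#' @param vessel_radius_px Lumen radius in pixels (positive integer).
#' @param peak_velocity Centre-line peak velocity, cm/s. May exceed `venc`
#'   only when aliasing is being simulated on purpose.
#' @param waveform Per-cardiac-phase velocity scale factors (length
#'   `n_phases`). Default: flat (steady flow).
#' @param venc Velocity-encoding limit, cm/s (the velocity mapped to phase
#'   \eqn{\pi}).
#' @param pixel_spacing In-plane pixel edge, mm.
#' @param slice_thickness Slice thickness, mm (metadata only).
#' @param n_phases Number of cardiac phases.
#' @param noise_sd_phase SD of zero-mean Gaussian phase noise, radians.
#' @param background_offset Constant phase offset added everywhere, radians
#'   (models an uncorrected eddy-current/background phase).
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(vessel_radius_px,
                         peak_velocity,
                         venc,
                         waveform = NULL,
                         pixel_spacing = 1.0,
                         slice_thickness = 5.0,
                         n_phases = 15L,
                         noise_sd_phase = 0,
                         background_offset = 0,
                         seed = 1L) {
  .check(is.numeric(vessel_radius_px) && length(vessel_radius_px) == 1 &&
           vessel_radius_px >= 1 && vessel_radius_px == round(vessel_radius_px),
         "vessel_radius_px must be a positive integer")
  .check(is.numeric(venc) && length(venc) == 1 && venc > 0, "venc must be > 0")
  .check(is.numeric(n_phases) && n_phases >= 1, "n_phases must be >= 1")
  .check(pixel_spacing > 0, "pixel_spacing must be > 0")
  .check(noise_sd_phase >= 0, "noise_sd_phase must be >= 0")
  if (is.null(waveform)) waveform <- rep(1, n_phases)
  .check(length(waveform) == n_phases, "waveform length must equal n_phases")
  structure(list(vessel_radius_px = as.integer(vessel_radius_px),
                 peak_velocity = peak_velocity, waveform = waveform,
                 venc = venc, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness,
                 n_phases = as.integer(n_phases),
                 noise_sd_phase = noise_sd_phase,
                 background_offset = background_offset,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a cine phase-contrast phantom series
#'
#' Builds a `cine_series`: magnitude and phase stacks
#' (`n_phases x rows x cols`). In-vessel velocity follows a parabolic profile
#' \eqn{v(\rho) = v_{peak}\,(1 - (\rho/R)^2)} scaled per phase by the
#' waveform; in-vessel phase is \eqn{\pi v / VENC} with the constant
#' background offset added everywhere, Gaussian phase noise added, and the
#' result wrapped to \eqn{(-\pi, \pi]}. Magnitude is high inside the lumen and
#' low outside. The true lumen and a static background band are attached as
#' masks for downstream ROI use.
#'
#' @param spec A [phantom_spec()].
#' @return A `cine_series` list: `magnitude`, `phase` (arrays), `venc`,
#'   `pixel_spacing`, `n_phases`, `heart_rate`, `lumen` and `static_mask`
#'   logical matrices.
#' @export
make_flow_phantom <- function(spec) {
  .check(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  r <- spec$vessel_radius_px
  n <- 2L * r + 9L                      # lumen + margin for background/static ROI
  ctr <- (n + 1) / 2
  xx <- matrix(rep(seq_len(n), each = n), n, n)   # column index
  yy <- matrix(rep(seq_len(n), times = n), n, n)  # row index
  rho2 <- ((xx - ctr)^2 + (yy - ctr)^2) / r^2
  lumen <- rho2 <= 1
  profile <- ifelse(lumen, 1 - rho2, 0)

  set.seed(spec$seed)
  mag <- array(0, dim = c(spec$n_phases, n, n))
  phs <- array(0, dim = c(spec$n_phases, n, n))
  for (k in seq_len(spec$n_phases)) {
    v <- spec$peak_velocity * spec$waveform[k] * profile
    phi <- pi * v / spec$venc + spec$background_offset
    if (spec$noise_sd_phase > 0)
      phi <- phi + matrix(stats::rnorm(n * n, 0, spec$noise_sd_phase), n, n)
    phs[k, , ] <- .wrap_phase(phi)
    mag[k, , ] <- ifelse(lumen, 100, 10)
  }
  static_mask <- rho2 > ((r + 2) / r)^2   # background band, clear of the lumen
  structure(list(magnitude = mag, phase = phs, venc = spec$venc,
                 pixel_spacing = spec$pixel_spacing,
                 slice_thickness = spec$slice_thickness,
                 n_phases = spec$n_phases, heart_rate = NA_real_,
                 lumen = lumen, static_mask = static_mask, seed = spec$seed),
            class = "cine_series")
}

#' Specification for a T2-prepared phantom
#'
#' @param t2_ms True blood T2, ms (> 0).
#' @param s0 Fully-recovered signal, arbitrary units (> 0).
#' @param prep_times_ms Strictly increasing T2 preparation times, ms.
#'   Default: the six-point protocol 32..192 ms.
#' @param noise_sd SD of additive Gaussian signal noise.
#' @param vessel_radius_px Lumen radius in pixels.
#' @param seed Integer seed.
#' @return An object of class `t2_phantom_spec`.
#' @export
t2_phantom_spec <- function(t2_ms, s0,
                            prep_times_ms = c(32, 64, 96, 128, 160, 192),
                            noise_sd = 0, vessel_radius_px = 10L, seed = 1L) {
  .check(is.numeric(t2_ms) && t2_ms > 0, "t2_ms must be > 0")
  .check(is.numeric(s0) && s0 > 0, "s0 must be > 0")
  .check(length(prep_times_ms) >= 1, "prep_times_ms must be non-empty")
  .check(all(prep_times_ms > 0) && all(diff(prep_times_ms) > 0),
         "prep_times_ms must be strictly increasing and positive")
  .check(noise_sd >= 0, "noise_sd must be >= 0")
  .check(vessel_radius_px >= 1, "vessel_radius_px must be >= 1")
  structure(list(t2_ms = t2_ms, s0 = s0, prep_times_ms = prep_times_ms,
                 noise_sd = noise_sd,
                 vessel_radius_px = as.integer(vessel_radius_px),
                 seed = as.integer(seed)),
            class = "t2_phantom_spec")
}

#' Generate a T2-prepared image series phantom
#'
#' One image per preparation time; in-vessel signal decays as
#' \eqn{S(t) = S_0 e^{-t/T_2}}, background is zero, Gaussian noise is added
#' everywhere. Seeded and reproducible.
#'
#' @param spec A [t2_phantom_spec()].
#' @return A `t2_series` list: `images` (prep-index x rows x cols),
#'   `prep_times_ms`, plus the true `lumen` mask.
#' @export
make_t2_phantom <- function(spec) {
  .check(inherits(spec, "t2_phantom_spec"), "spec must be a t2_phantom_spec")
  r <- spec$vessel_radius_px
  n <- 2L * r + 9L
  ctr <- (n + 1) / 2
  xx <- matrix(rep(seq_len(n), each = n), n, n)
  yy <- matrix(rep(seq_len(n), times = n), n, n)
  lumen <- ((xx - ctr)^2 + (yy - ctr)^2) <= r^2
  set.seed(spec$seed)
  np <- length(spec$prep_times_ms)
  img <- array(0, dim = c(np, n, n))
  for (k in seq_len(np)) {
    s <- ifelse(lumen, spec$s0 * exp(-spec$prep_times_ms[k] / spec$t2_ms), 0)
    if (spec$noise_sd > 0)
      s <- s + matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n)
    img[k, , ] <- s
  }
  structure(list(images = img, prep_times_ms = spec$prep_times_ms,
                 lumen = lumen, seed = spec$seed),
            class = "t2_series")
}

#' Generate a labelled volume for volumetry
#'
#' Builds a 3-D label map (0 background, 1 fetal body, 2 brain) with exactly
#' the requested voxel counts; the brain label is placed inside the fetal
#' body (brain is a subset of the body, so `fetal_voxels` counts the brain
#' voxels too).
#'
#' @param shape Integer length-3 grid dimensions.
#' @param fetal_voxels Total fetal-body voxel count (including brain).
#' @param brain_voxels Brain voxel count (`<= fetal_voxels`).
#' @param voxel_size_mm Length-3 voxel spacing, mm.
#' @return A `volume_segmentation` list: `label_map` (3-D integer array),
#'   `spacing_mm`, `voxel_volume_mm3`.
#' @export
make_label_volume <- function(shape, fetal_voxels, brain_voxels,
                              voxel_size_mm = c(1, 1, 1)) {
  .check(length(shape) == 3 && all(shape >= 1), "shape must be 3 positive dims")
  .check(length(voxel_size_mm) == 3 && all(voxel_size_mm > 0),
         "voxel_size_mm must be 3 positive spacings")
  total <- prod(shape)
  .check(brain_voxels >= 0 && fetal_voxels >= 0, "voxel counts must be >= 0")
  .check(brain_voxels <= fetal_voxels,
         "brain_voxels must not exceed fetal_voxels")
  .check(fetal_voxels <= total, "fetal_voxels exceed the grid")
  lab <- integer(total)
  if (fetal_voxels > 0) lab[seq_len(fetal_voxels)] <- 1L
  if (brain_voxels > 0) lab[seq_len(brain_voxels)] <- 2L
  structure(list(label_map = array(lab, dim = shape),
                 spacing_mm = voxel_size_mm,
                 voxel_volume_mm3 = prod(voxel_size_mm)),
            class = "volume_segmentation")
}
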