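# Blood T2 relaxometry oximetry ----------------------------------------------

#' Erode a vessel mask to its central area fraction
#'
#' Keeps the mask pixels with the largest distance to the mask boundary such
#' that the retained area is the largest value not exceeding
#' `fraction * area` (at least one pixel); ties in distance are broken by
#' row-major pixel index. This reproduces the oximetry ROI rule of covering
#' only the central portion (60% by default) of the vessel, and is well
#' defined for non-circular masks.
#'
#' @param mask Logical matrix (non-empty).
#' @param fraction Area fraction to retain, in (0, 1].
#' @return Logical matrix, a subset of `mask`.
#' @export
erode_to_central_fraction <- function(mask, fraction = 0.6) {
  mask <- mask > 0
  .check(any(mask), "mask is empty")
  .check(is.numeric(fraction) && fraction > 0 && fraction <= 1,
         "fraction must be in (0, 1]")
  if (fraction == 1) return(mask)
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
  idx <- which(mask)
  rowmajor <- (row(mask)[idx] - 1L) * ncol(mask) + col(mask)[idx]
  ord <- order(-d[idx], rowmajor)
  keep_n <- max(1L, floor(fraction * length(idx)))
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[idx[ord[seq_len(keep_n)]]] <- TRUE
  out
}

#' Mean in-ROI signal per preparation time
#'
#' @param series A `t2_series` (stack `prep-index x rows x cols`).
#' @param roi Logical matrix; non-empty.
#' @return Numeric vector of per-prep-time mean signals.
#' @export
mean_roi_signal <- function(series, roi) {
  .check(inherits(series, "t2_series"), "series must be a t2_series")
  roi <- roi > 0
  .check(any(roi), "ROI is empty")
  .check(all(dim(series$images)[2:3] == dim(roi)), "ROI/image shape mismatch")
  vapply(seq_len(dim(series$images)[1]),
         function(k) mean(series$images[k, , ][roi]), numeric(1))
}

# Upper bound used to flag a non-decaying (degenerate) fit.
.T2_UPPER_MS <- 1e5

#' Fit a mono-exponential T2 decay
#'
#' Fits \eqn{S(t) = S_0 e^{-t/T_2}} to per-preparation-time signal means.
#' The log-linear method is ordinary least squares on \eqn{\log S}; the
#' iterative method minimises the untransformed residual sum of squares
#' (Levenberg-Marquardt), initialised from the log-linear solution so it is
#' deterministic. Both agree exactly on noiseless data; the iterative fit
#' weights noise correctly at low SNR and is the default.
#'
#' @param signal_means Per-prep-time mean signals.
#' @param prep_times_ms Preparation times, ms (strictly increasing, >= 3).
#' @param method `"iterative"` (default) or `"loglinear"`.
#' @return A `t2_fit` list: `s0`, `t2_ms`, `r_squared`, `residuals`,
#'   `at_bound` (TRUE when the data show no measurable decay and `t2_ms` is
#'   capped), `method`.
#' @export
fit_t2 <- function(signal_means, prep_times_ms,
                   method = c("iterative", "loglinear")) {
  method <- match.arg(method)
  .check(length(signal_means) == length(prep_times_ms),
         "signal and prep-time lengths differ")
  .check(length(prep_times_ms) >= 3, "need at least 3 preparation times")
  .check(all(diff(prep_times_ms) > 0) && all(prep_times_ms > 0),
         "prep_times_ms must be strictly increasing and positive")
  if (any(signal_means <= 0) && method == "loglinear")
    stop("log-linear fit requires strictly positive signals", call. = FALSE)

  # log-linear seed (on the positive subset for the iterative method)
  pos <- signal_means > 0
  if (sum(pos) >= 2) {
    ll <- stats::lm.fit(cbind(1, prep_times_ms[pos]), log(signal_means[pos]))
    slope <- ll$coefficients[2]
    s0_ll <- exp(ll$coefficients[1])
  } else {
    slope <- -1 / 100
    s0_ll <- max(abs(signal_means))
  }
  at_bound <- !is.finite(slope) || slope >= -1 / .T2_UPPER_MS
  t2_ll <- if (at_bound) .T2_UPPER_MS else -1 / slope

  finish <- function(s0, t2, at_bound) {
    fitted <- s0 * exp(-prep_times_ms / t2)
    res <- signal_means - fitted
    sst <- sum((signal_means - mean(signal_means))^2)
    r2 <- if (sst == 0) NA_real_ else 1 - sum(res^2) / sst
    structure(list(s0 = unname(s0), t2_ms = unname(t2), r_squared = r2,
                   residuals = res, at_bound = at_bound, method = method),
              class = "t2_fit")
  }
  if (method == "loglinear" || at_bound) return(finish(s0_ll, t2_ll, at_bound))

  df <- data.frame(t = prep_times_ms, s = signal_means)
  fit <- tryCatch(
    minpack.lm::nlsLM(s ~ s0 * exp(-t / t2), data = df,
                      start = list(s0 = unname(s0_ll), t2 = unname(t2_ll)),
                      lower = c(0, 1e-3), upper = c(Inf, .T2_UPPER_MS),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("T2 fit did not converge (last log-linear iterate: t2 = ",
           signif(t2_ll, 6), " ms): ", conditionMessage(e), call. = FALSE))
  cf <- stats::coef(fit)
  finish(cf[["s0"]], cf[["t2"]], cf[["t2"]] >= .T2_UPPER_MS * (1 - 1e-9))
}

#' T2-to-saturation calibration model
#'
#' Luz-Meiboom-type quadratic-in-desaturation relation
#' \eqn{1/T_2 = 1/T_2^{plateau} + K (1 - Y)^2}: blood T2 rises with oxygen
#' saturation because deoxyhaemoglobin is paramagnetic. The numeric
#' constants of the species-specific (sheep-blood) calibration are not
#' published alongside the method; the defaults here are provisional,
#' order-of-magnitude values for fetal blood at 3 T and must be replaced
#' with a laboratory calibration for quantitative use. An optional linear
#' haematocrit adjustment rescales K.
#'
#' @param t2_plateau_ms T2 at full saturation, ms (> 0).
#' @param k_rate Desaturation rate constant, 1/ms (>= 0).
#' @param hct_ref,hct_slope Optional haematocrit adjustment:
#'   `K_eff = k_rate * (1 + hct_slope * (hct - hct_ref))`.
#' @return An object of class `t2_calibration`.
#' @export
t2_calibration <- function(t2_plateau_ms = 250, k_rate = 0.03,
                           hct_ref = NULL, hct_slope = NULL) {
  .check(t2_plateau_ms > 0, "t2_plateau_ms must be > 0")
  .check(k_rate >= 0, "k_rate must be >= 0")
  structure(list(t2_plateau_ms = t2_plateau_ms, k_rate = k_rate,
                 hct_ref = hct_ref, hct_slope = hct_slope,
                 provisional = TRUE),
            class = "t2_calibration")
}

.k_eff <- function(calib, hct = NULL) {
  k <- calib$k_rate
  if (!is.null(hct) && !is.null(calib$hct_slope) && !is.null(calib$hct_ref))
    k <- k * (1 + calib$hct_slope * (hct - calib$hct_ref))
  .check(k >= 0, "effective K must be >= 0 after haematocrit adjustment")
  k
}

#' Forward calibration: saturation to T2
#'
#' @param y Oxygen saturation fraction(s) in [0, 1].
#' @param calib A [t2_calibration()].
#' @param hct Optional haematocrit for the K adjustment.
#' @return T2 in ms (vectorised over `y`).
#' @export
so2_to_t2 <- function(y, calib, hct = NULL) {
  .check(inherits(calib, "t2_calibration"), "calib must be a t2_calibration")
  .check(all(y >= 0 & y <= 1), "y must lie in [0, 1]")
  k <- .k_eff(calib, hct)
  1 / (1 / calib$t2_plateau_ms + k * (1 - y)^2)
}

#' Invert the calibration: T2 to saturation
#'
#' Inverts \eqn{1/T_2 = 1/T_2^{plateau} + K(1-Y)^2} for the root in [0, 1].
#' Unclamped roots outside [0, 1] by at most `tol` (default 0.02) are clamped
#' with `clamped = TRUE`; beyond that the input is treated as unphysical and
#' an error is raised.
#'
#' @param t2_ms Fitted blood T2, ms (> 0; vectorised).
#' @param calib A [t2_calibration()].
#' @param hct Optional haematocrit for the K adjustment.
#' @param tol Clamping tolerance on the saturation scale.
#' @return Numeric vector of saturations in [0, 1] with attribute `clamped`
#'   (logical vector).
#' @export
t2_to_so2 <- function(t2_ms, calib, hct = NULL, tol = 0.02) {
  .check(inherits(calib, "t2_calibration"), "calib must be a t2_calibration")
  .check(all(t2_ms > 0), "t2_ms must be > 0")
  k <- .k_eff(calib, hct)
  delta <- (1 / t2_ms - 1 / calib$t2_plateau_ms)
  if (k == 0) {
    bad <- abs(delta) > 1e-12
    if (any(bad))
      stop("calibration K = 0 cannot map T2 != T2 plateau to a saturation",
           call. = FALSE)
    y <- rep(1, length(t2_ms))
    attr(y, "clamped") <- rep(FALSE, length(y))
    return(y)
  }
  # signed extension of y = 1 - sqrt(delta/K): negative delta (T2 above the
  # plateau) lands above 1, large positive delta lands below 0
  y <- 1 - sign(delta) * sqrt(abs(delta) / k)
  if (any(y > 1 + tol))
    stop("T2 exceeds the calibration plateau beyond tolerance (unphysical)",
         call. = FALSE)
  if (any(y < -tol))
    stop("T2 below the full-desaturation limit beyond tolerance", call. = FALSE)
  clamped <- y < 0 | y > 1
  y <- pmin(1, pmax(0, y))
  attr(y, "clamped") <- clamped
  y
}

#' Estimate vessel saturation from a T2-prepared series
#'
#' Chains the central-fraction ROI erosion, per-prep-time mean signal,
#' mono-exponential T2 fit and calibration inversion.
#'
#' @param series A `t2_series`.
#' @param roi Lumen mask (default the series' true lumen).
#' @param calib A [t2_calibration()].
#' @param central_fraction ROI area fraction retained (default 0.6).
#' @param method Fit method passed to [fit_t2()].
#' @return List with `y`, `t2_fit` and the eroded `roi`.
#' @export
measure_saturation <- function(series, roi = NULL, calib = t2_calibration(),
                               central_fraction = 0.6,
                               method = "iterative") {
  roi <- roi %||% series$lumen
  core <- erode_to_central_fraction(roi, central_fraction)
  fit <- fit_t2(mean_roi_signal(series, core), series$prep_times_ms,
                method = method)
  y <- t2_to_so2(fit$t2_ms, calib)
  list(y = as.numeric(y), clamped = attr(y, "clamped"), t2_fit = fit,
       roi = core)
}
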