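#' Detector model
#'
#' Pixel pitch, blur (presampling MTF and Gaussian focal-spot kernel),
#' noise power spectrum and exposure calibration of the detector. The
#' default is an ideal detector: MTF identically 1, flat NPS, no blur and
#' no noise — measured curves are opt-in via [read_frequency_curve()].
#'
#' @param pixel_pitch pixel size in metres.
#' @param mtf_curve `NULL` (ideal) or a data frame with columns `freq`
#'   (cycles/m, ascending from 0) and `value`, with `value[freq == 0] == 1`.
#' @param nps_curve `NULL` (flat) or a data frame like `mtf_curve` with
#'   nonnegative values.
#' @param exposure_calibration mean pixel value per unit entrance air kerma
#'   (1/mGy), > 0.
#' @param focal_spot_sigma Gaussian focal-spot blur standard deviation in
#'   metres (default 0).
#' @param noise logical: add NPS-shaped Poisson-scaled noise?
#' @param eak entrance air kerma per frame in mGy (default 1e3, chosen high
#'   so noise is negligible when enabled).
#' @return an object of class `detector_model`.
#' @export
detector_model <- function(pixel_pitch, mtf_curve = NULL, nps_curve = NULL,
                           exposure_calibration = 1, focal_spot_sigma = 0,
                           noise = FALSE, eak = 1e3) {
  if (pixel_pitch <= 0) stop_invalid("'pixel_pitch' must be > 0")
  if (exposure_calibration <= 0)
    stop_invalid("'exposure_calibration' must be > 0")
  if (focal_spot_sigma < 0) stop_invalid("'focal_spot_sigma' must be >= 0")
  check_curve <- function(cv, name, unit_at_zero) {
    if (is.null(cv)) return(NULL)
    cv <- as.data.frame(cv)
    names(cv)[1:2] <- c("freq", "value")
    if (nrow(cv) < 1L || any(!is.finite(cv$freq)) || any(!is.finite(cv$value)))
      stop_invalid("'", name, "' must be a finite two-column table")
    if (is.unsorted(cv$freq, strictly = TRUE) || any(cv$freq < 0))
      stop_invalid("'", name, "' frequencies must be nonnegative and strictly increasing")
    if (any(cv$value < 0)) stop_invalid("'", name, "' values must be >= 0")
    if (unit_at_zero && abs(curve_value(cv, 0) - 1) > 1e-6)
      stop_invalid("'", name, "' must equal 1 at zero frequency")
    cv
  }
  structure(list(
    pixel_pitch = pixel_pitch,
    mtf_curve = check_curve(mtf_curve, "mtf_curve", TRUE),
    nps_curve = check_curve(nps_curve, "nps_curve", FALSE),
    exposure_calibration = exposure_calibration,
    focal_spot_sigma = focal_spot_sigma,
    noise = isTRUE(noise), eak = eak
  ), class = "detector_model")
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf(paste0(
    "detector_model: pixel %.0f um, MTF %s, NPS %s,\n",
    "  focal-spot sigma %.1f um, calibration %.3g /mGy, EAK %.3g mGy, noise %s\n"),
    x$pixel_pitch * 1e6,
    if (is.null(x$mtf_curve)) "ideal (=1)" else "tabulated",
    if (is.null(x$nps_curve)) "flat" else "tabulated",
    x$focal_spot_sigma * 1e6, x$exposure_calibration, x$eak,
    if (x$noise) "on" else "off"))
  invisible(x)
}

# linear interpolation on a tabulated curve, clamped at both ends
curve_value <- function(curve, freq) {
  approx(curve$freq, curve$value, xout = abs(freq), rule = 2)$y
}

#' Read a measured MTF or NPS curve from a two-column text file
#'
#' Loads and validates a tabulated frequency curve (delimited text,
#' frequency in cycles/mm in the first column). MTF curves are normalized
#' to 1 at zero frequency. Estimation from raw edge or flat-field images is
#' out of scope — only curve ingestion is supported.
#'
#' @param path file path; delimited numeric text, comment lines starting
#'   with `#` are skipped.
#' @param normalize_zero if `TRUE`, divide by the zero-frequency value
#'   (used for MTF curves).
#' @return data frame with columns `freq` (cycles/m) and `value`.
#' @export
read_frequency_curve <- function(path, normalize_zero = FALSE) {
  tab <- tryCatch(
    read.table(path, comment.char = "#", header = FALSE),
    error = function(e) stop_invalid("cannot parse curve file '", path, "': ",
                                     conditionMessage(e)))
  if (ncol(tab) < 2L || nrow(tab) < 1L)
    stop_invalid("curve file '", path, "' must have two numeric columns")
  cv <- data.frame(freq = as.numeric(tab[[1]]) * 1e3,  # cycles/mm -> cycles/m
                   value = as.numeric(tab[[2]]))
  if (any(!is.finite(cv$freq)) || any(!is.finite(cv$value)))
    stop_invalid("curve file '", path, "' contains non-numeric entries")
  if (is.unsorted(cv$freq, strictly = TRUE))
    stop_invalid("curve file '", path, "' frequency axis must be strictly increasing")
  if (normalize_zero) {
    v0 <- curve_value(cv, 0)
    if (v0 <= 0) stop_invalid("curve '", path, "' has nonpositive zero-frequency value")
    cv$value <- cv$value / v0
  }
  cv
}

#' Integrate fine-grid intensity over detector pixels
#'
#' Sums the finely sampled intensity within each pixel footprint of the
#' field of view. Total intensity over the field of view is conserved.
#'
#' @param intensity fine intensity matrix (x along rows).
#' @param geometry a [gi_geometry()]; supplies pixel pitch, fine spacing and
#'   field-of-view placement.
#' @param grid optional precomputed `fine_grid(geometry)` (or the matching
#'   1-row variant).
#' @param step_position analyzer position recorded with the frame.
#' @return an object of class `pixel_image`: list with `values`
#'   (fov_x x fov_y matrix) and `step_position`.
#' @export
bin_to_pixels <- function(intensity, geometry, grid = NULL, step_position = 0) {
  if (is.null(grid)) grid <- fine_grid(geometry)
  k <- grid$samples_per_pixel
  sub <- intensity[grid$fov_ix, grid$fov_iy, drop = FALSE]
  npx <- nrow(sub) %/% k
  if (npx * k != nrow(sub))
    stop_invalid("pixel pitch is not commensurate with the fine grid")
  if (ncol(sub) == 1L) {
    # 1-D fast mode: a single y-line stands for the pixel row
    vals <- matrix(colSums(matrix(sub[, 1L], nrow = k)), ncol = 1L)
  } else {
    npy <- ncol(sub) %/% k
    if (npy * k != ncol(sub))
      stop_invalid("pixel pitch is not commensurate with the fine grid")
    m <- colSums(array(sub, c(k, npx * k * npy)))        # sum within x
    m <- matrix(m, nrow = npx)                            # npx x (k*npy)
    vals <- matrix(colSums(array(t(m), c(k, npy * npx))), # sum within y
                   nrow = npy)
    vals <- t(vals)                                       # npx x npy
  }
  structure(list(values = vals, step_position = step_position),
            class = "pixel_image")
}

#' Scale a pixel image to exposure-calibrated pixel values
#'
#' Applies the linear pixel-value/exposure relation
#' `S_PV = calibration * eak`, normalized to the mean no-object (reference)
#' pixel intensity so that an open-field pixel reads `calibration * eak`.
#'
#' @param image a `pixel_image`.
#' @param eak entrance air kerma in mGy (>= 0).
#' @param calibration pixel value per mGy (> 0).
#' @param reference_mean mean reference (no-object, no-grating) pixel
#'   intensity used for normalization.
#' @return a `pixel_image`.
#' @export
scale_exposure <- function(image, eak, calibration = 1, reference_mean = 1) {
  if (eak < 0) stop_invalid("'eak' must be >= 0")
  image$values <- image$values * (calibration * eak / reference_mean)
  image
}

#' Apply detector MTF and focal-spot blur to a pixel image
#'
#' Fourier-domain multiplication by the (radially interpolated) presampling
#' MTF and by the transform of a Gaussian of standard deviation
#' `focal_spot_sigma`. Both filters are 1 at zero frequency, so the image
#' mean is preserved.
#'
#' @param image a `pixel_image`.
#' @param model a [detector_model()].
#' @return a `pixel_image`.
#' @export
apply_system_blur <- function(image, model) {
  if (is.null(model$mtf_curve) && model$focal_spot_sigma == 0) return(image)
  v <- image$values
  fx <- fft_freq(nrow(v), model$pixel_pitch)
  fy <- fft_freq(ncol(v), model$pixel_pitch)
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  filt <- exp(-2 * pi^2 * model$focal_spot_sigma^2 * fr^2)
  if (!is.null(model$mtf_curve))
    filt <- filt * matrix(curve_value(model$mtf_curve, fr), nrow(v), ncol(v))
  image$values <- Re(fft(fft(v) * filt, inverse = TRUE)) / length(v)
  image
}

#' Add NPS-shaped, Poisson-scaled noise to a pixel image
#'
#' Draws a unit-variance zero-mean Gaussian field, filters its transform by
#' the square root of the NPS, rescales the filtered field to unit
#' empirical standard deviation, multiplies pointwise by the square root of
#' the pixel intensity (Poisson scaling) and adds it to the image. With
#' `model$noise = FALSE` the image is returned unchanged.
#'
#' @param image a `pixel_image` with nonnegative values.
#' @param model a [detector_model()].
#' @param seed integer RNG seed.
#' @return a `pixel_image`.
#' @export
add_noise <- function(image, model, seed = NULL) {
  if (!model$noise) return(image)
  v <- image$values
  if (any(v < 0)) stop_invalid("noise model requires nonnegative pixel values")
  r <- with_seed(seed, matrix(rnorm(length(v)), nrow(v), ncol(v)))
  if (!is.null(model$nps_curve)) {
    fx <- fft_freq(nrow(v), model$pixel_pitch)
    fy <- fft_freq(ncol(v), model$pixel_pitch)
    fr <- sqrt(outer(fx^2, fy^2, "+"))
    filt <- matrix(sqrt(curve_value(model$nps_curve, fr)), nrow(v), ncol(v))
    n <- Re(fft(fft(r) * filt, inverse = TRUE)) / length(r)
  } else {
    n <- r
  }
  sigma_n <- sd(as.vector(n))
  if (sigma_n > 0) n <- n / sigma_n
  image$values <- v + n * sqrt(v)
  image
}
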