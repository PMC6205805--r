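#' Acquire a phase-stepping stack
#'
#' Runs the full wave chain once per analyzer step: (optional) object
#' transmission and phase grating G1 at the object plane, Fresnel
#' propagation to the G2 plane, optional Gaussian source blur, then for
#' each of `n_steps` uniform G2 positions over one `p2` period the masked
#' intensity is binned to detector pixels, exposure-scaled, blurred and
#' (optionally) noised.
#'
#' The costly propagation is performed once; stepping only re-masks the
#' intensity at the G2 plane. With `phantom = NULL` the reference (no
#' object) stack is produced; the reference field is uniform along y, so it
#' is computed on a single y-line and broadcast.
#'
#' @param geometry a [gi_geometry()].
#' @param phantom a [generate_sphere_pack()] result, a `projected_object`,
#'   or `NULL` for the reference acquisition.
#' @param detector a [detector_model()]; defaults to an ideal detector at
#'   the geometry's pixel pitch.
#' @param materials list with elements `air` and `tissue`
#'   ([material_optics()]); required when `phantom` is given.
#' @param n_steps number of phase steps N_G2 (>= 3, default 8).
#' @param seed RNG seed for detector noise (unused when noise is off).
#' @param overlap chord overlap semantics passed to [project_air_path()]
#'   when `phantom` is a sphere pack; default `"sum"`, the lung-model
#'   projection semantics.
#' @return an object of class `phase_step_stack`: list with `frames`
#'   (fov_x x fov_y x n_steps array), `step_positions`, `n_steps`,
#'   `geometry`.
#' @export
acquire_stack <- function(geometry, phantom = NULL, detector = NULL,
                          materials = NULL, n_steps = 8L, seed = NULL,
                          overlap = "sum") {
  stopifnot(inherits(geometry, "gi_geometry"))
  if (n_steps < 3L) stop_invalid("'n_steps' must be at least 3")
  if (is.null(detector))
    detector <- detector_model(pixel_pitch = geometry$pixel_pitch)
  reference <- is.null(phantom)
  grid <- if (reference) fine_grid(geometry, ny = 1L) else fine_grid(geometry)

  if (reference) {
    amp <- matrix(1 + 0i, grid$nx, grid$ny)
  } else {
    if (is.null(materials) || is.null(materials$air) || is.null(materials$tissue))
      stop_invalid("'materials' with elements 'air' and 'tissue' is required ",
                   "for an object acquisition")
    proj <- if (inherits(phantom, "projected_object")) phantom
            else project_air_path(phantom, x = grid$x, y = grid$y,
                                  overlap = overlap)
    amp <- object_transmission(proj, materials$tissue, materials$air,
                               geometry$wavelength)
  }
  fld <- wavefield(amp, grid$spacing, x = grid$x)
  fld <- apply_phase_grating(fld, geometry$p1, geometry$duty_g1,
                             geometry$phase_shift)
  fld <- propagate(fld, geometry$distance_d, geometry$wavelength)
  if (geometry$source_sigma > 0)
    fld <- apply_source_blur(fld, geometry$source_sigma)

  steps <- (seq_len(n_steps) - 1L) * geometry$p2 / n_steps
  k <- grid$samples_per_pixel
  ref_norm <- k^2  # unit plane wave integrated over one pixel, no grating
  npx <- geometry$fov_pixels[1]
  npy <- geometry$fov_pixels[2]
  frames <- array(0, c(npx, npy, n_steps))
  for (s in seq_len(n_steps)) {
    intens <- apply_analyzer_grating(fld, geometry$p2, steps[s],
                                     geometry$duty_g2,
                                     geometry$bar_transmission)
    img <- bin_to_pixels(intens, geometry, grid = grid,
                         step_position = steps[s])
    if (reference && grid$ny == 1L) {
      img$values <- matrix(img$values[, 1L] * k, npx, npy)  # broadcast y-line
    }
    img <- scale_exposure(img, detector$eak, detector$exposure_calibration,
                          reference_mean = ref_norm)
    img <- apply_system_blur(img, detector)
    img <- add_noise(img, detector,
                     seed = if (is.null(seed)) NULL else seed + s)
    frames[, , s] <- img$values
  }
  structure(list(frames = frames, step_positions = steps,
                 n_steps = as.integer(n_steps), geometry = geometry),
            class = "phase_step_stack")
}

#' @export
print.phase_step_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("phase_step_stack: %d x %d pixels, %d steps over p2 = %.3f um\n",
              d[1], d[2], x$n_steps, x$geometry$p2 * 1e6))
  invisible(x)
}

#' Fourier retrieval of the stepping curve
#'
#' Per pixel, discrete Fourier analysis of intensity versus analyzer step:
#' `a0` is the stepping-curve mean, `a1` the first-harmonic amplitude
#' (so visibility `v = 2*a1/a0`) and `phi` the first-harmonic phase. For a
#' pure sinusoid `I_k = a0*(1 + v*cos(2*pi*k/N + phi))` the identity is
#' exact for any `N >= 3`.
#'
#' @param stack a [acquire_stack()] result (or any list with a 3-d `frames`
#'   array).
#' @return list of matrices `a0`, `a1`, `phi`, `visibility`.
#' @export
fourier_retrieve <- function(stack) {
  fr <- stack$frames
  stopifnot(length(dim(fr)) == 3L)
  n <- dim(fr)[3]
  if (n < 3L) stop_invalid("at least 3 phase steps are required")
  m <- matrix(fr, ncol = n)
  w <- exp(-2i * pi * (seq_len(n) - 1L) / n)
  x1 <- as.vector(m %*% w)
  a0 <- rowMeans(m)
  if (any(a0 == 0)) stop_invalid("degenerate pixel: zero mean stepping curve")
  a1 <- Mod(x1) / n
  dims <- dim(fr)[1:2]
  list(a0 = matrix(a0, dims[1], dims[2]),
       a1 = matrix(a1, dims[1], dims[2]),
       phi = matrix(Arg(x1), dims[1], dims[2]),
       visibility = matrix(2 * a1 / a0, dims[1], dims[2]))
}

#' Transmission, differential-phase and dark-field images
#'
#' Combines object and reference stepping stacks into the three grating
#' interferometry images: per pixel, transmission `T = a0_obj/a0_ref`,
#' dark field `df = v_obj/v_ref` and differential phase
#' `wrap(phi_obj - phi_ref)` in `(-pi, pi]`. Dark-field values marginally
#' above 1 (noise) are kept so averages stay unbiased.
#'
#' @param object_stack,reference_stack matching [acquire_stack()] results.
#' @return an object of class `gi_images`: list with matrices
#'   `transmission`, `differential_phase`, `dark_field`,
#'   `reference_visibility`.
#' @export
compute_gi_images <- function(object_stack, reference_stack) {
  if (object_stack$n_steps != reference_stack$n_steps ||
      !isTRUE(all.equal(dim(object_stack$frames), dim(reference_stack$frames))))
    stop_invalid("object and reference stacks must share geometry and step grid")
  obj <- fourier_retrieve(object_stack)
  ref <- fourier_retrieve(reference_stack)
  if (any(ref$visibility <= 1e-9))
    stop_invalid("zero reference visibility: no carrier fringe to analyze")
  dphi <- obj$phi - ref$phi
  dphi <- dphi - 2 * pi * floor((dphi + pi) / (2 * pi))  # wrap to (-pi, pi]
  structure(list(
    transmission = obj$a0 / ref$a0,
    differential_phase = dphi,
    dark_field = obj$visibility / ref$visibility,
    reference_visibility = ref$visibility
  ), class = "gi_images")
}

#' @export
print.gi_images <- function(x, ...) {
  cat(sprintf(paste0(
    "gi_images (%d x %d pixels)\n",
    "  transmission: mean %.4f   dark field: mean %.4f\n",
    "  reference visibility: mean %.4f\n"),
    nrow(x$dark_field), ncol(x$dark_field), mean(x$transmission),
    mean(x$dark_field), mean(x$reference_visibility)))
  invisible(x)
}

#' Export GI images as 32-bit float TIFFs plus a CSV summary
#'
#' TIFF samples are stored rescaled to `[0, 1]`; the per-image minimum and
#' maximum needed to undo the rescaling are recorded in the CSV summary
#' alongside the mean and standard deviation.
#'
#' @param images a [compute_gi_images()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the paths written.
#' @export
write_gi_images <- function(images, dir, prefix = "gi") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nms <- c("transmission", "differential_phase", "dark_field")
  paths <- character(0)
  if (requireNamespace("tiff", quietly = TRUE)) {
    for (nm in nms) {
      p <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
      v <- images[[nm]]
      rng <- range(v)
      v01 <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0 + 0.5
      tiff::writeTIFF(v01, p, bits.per.sample = 32L)
      paths <- c(paths, p)
    }
  }
  summ <- data.frame(
    image = nms,
    mean = vapply(images[nms], mean, numeric(1)),
    sd = vapply(images[nms], sd, numeric(1)),
    min = vapply(images[nms], min, numeric(1)),
    max = vapply(images[nms], max, numeric(1)))
  p <- file.path(dir, sprintf("%s_summary.csv", prefix))
  write.csv(summ, p, row.names = FALSE)
  invisible(c(paths, p))
}
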