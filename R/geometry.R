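#' Photon wavelength from energy
#'
#' Converts an x-ray photon energy to wavelength via `lambda = hc/E`
#' (hc = 1.23984193 keV nm).
#'
#' @param energy_keV photon energy in keV (scalar, > 0).
#' @return wavelength in metres.
#' @examples
#' wavelength_from_energy(27.7) # ~4.48e-11 m
#' @export
wavelength_from_energy <- function(energy_keV) {
  if (!is.numeric(energy_keV) || length(energy_keV) != 1L || energy_keV <= 0)
    stop_invalid("'energy_keV' must be a single positive number")
  .hc_keV_nm / energy_keV * 1e-9
}

#' Fractional Talbot distance of a pi-shift grating interferometer
#'
#' Distance from the phase grating G1 to the analyzer grating G2 at which the
#' pi-shift self-image fringe of period `p2` has maximum contrast:
#' `d = m * p2^2 / (2 * lambda)` with `m` an odd Talbot order.
#'
#' @param p2 fringe/G2 period in metres.
#' @param wavelength wavelength in metres.
#' @param m odd Talbot order (default 1).
#' @return inter-grating distance in metres.
#' @examples
#' talbot_distance(2e-6, wavelength_from_energy(27.7)) # ~0.0447 m
#' @export
talbot_distance <- function(p2, wavelength, m = 1L) {
  if (!is.numeric(p2) || length(p2) != 1L || p2 <= 0)
    stop_invalid("'p2' must be a single positive length")
  if (!is.numeric(wavelength) || length(wavelength) != 1L || wavelength <= 0)
    stop_invalid("'wavelength' must be a single positive length")
  if (length(m) != 1L || m < 1 || m %% 2 != 1)
    stop_invalid("Talbot order 'm' must be an odd positive integer")
  m * p2^2 / (2 * wavelength)
}

#' Autocorrelation length of a grating interferometer
#'
#' The structural length scale the setup is most sensitive to,
#' `d_auto = lambda * d / p2`. At the m-th Talbot distance this reduces to
#' `m * p2 / 2` independent of energy.
#'
#' @param wavelength wavelength in metres.
#' @param distance_d G1-to-G2 distance in metres.
#' @param p2 fringe period in metres.
#' @return autocorrelation length in metres.
#' @export
autocorrelation_length <- function(wavelength, distance_d, p2) {
  stopifnot(wavelength > 0, distance_d > 0, p2 > 0)
  wavelength * distance_d / p2
}

#' Interferometer geometry
#'
#' Bundles the grating pitches, design energy, Talbot order, inter-grating
#' distance, detector pixel pitch, fine sampling and field of view of a
#' Talbot interferometer. Unless `distance_d` is supplied it is set to the
#' fractional Talbot distance [talbot_distance()] for the design wavelength.
#'
#' @param p1 G1 (phase grating) pitch in metres. The plane-wave model uses
#'   the design ratio `p1 = 2*p2` (default), so the self-image fringe period
#'   `p1/2` equals the analyzer pitch; a physical diverging-beam pitch such
#'   as the 3.901 um prototype value corresponds to this after the beam
#'   magnification that matches the fringe to G2.
#' @param p2 G2/fringe pitch in metres.
#' @param design_energy_keV design photon energy in keV.
#' @param talbot_order odd Talbot order m.
#' @param distance_d optional explicit G1-to-G2 distance in metres.
#' @param pixel_pitch detector pixel size in metres; must be an integer
#'   multiple of the fine grid spacing `p2 / fine_sampling`.
#' @param fine_sampling fine samples per `p2` period (integer, >= 8).
#' @param fov_pixels field of view in pixels, length-2 integer (nx, ny).
#' @param duty_g1,duty_g2 grating duty cycles (open fraction), default 0.5.
#' @param phase_shift G1 phase shift in radians, default `pi`.
#' @param bar_transmission amplitude transmitted by the G2 bars (default 0,
#'   an ideal absorption grating).
#' @param guard_periods guard band, in `p2` periods, added on each side of
#'   the field of view before propagation (periodic boundary), default 32.
#' @param source_sigma standard deviation of the Gaussian source (G0
#'   aperture) blur applied to the complex amplitude, in metres; default 0
#'   (no source blur).
#' @return an object of class `gi_geometry`.
#' @export
gi_geometry <- function(p1 = 2 * p2, p2 = 2.000e-6,
                        design_energy_keV = 27.7, talbot_order = 1L,
                        distance_d = NULL, pixel_pitch = 100e-6,
                        fine_sampling = 16L, fov_pixels = c(5L, 5L),
                        duty_g1 = 0.5, duty_g2 = 0.5, phase_shift = pi,
                        bar_transmission = 0, guard_periods = 32L,
                        source_sigma = 0) {
  wl <- wavelength_from_energy(design_energy_keV)
  if (length(talbot_order) != 1L || talbot_order < 1 || talbot_order %% 2 != 1)
    stop_invalid("'talbot_order' must be an odd positive integer")
  if (abs(p1 - 2 * p2) > 0.05 * 2 * p2)
    stop_invalid("'p1' must equal 2*p2 to within 5% (pi-shift Talbot design)")
  if (fine_sampling < 8)
    stop_invalid("'fine_sampling' must be at least 8 samples per p2 period")
  if (is.null(distance_d))
    distance_d <- talbot_distance(p2, wl, talbot_order)
  spacing <- p2 / fine_sampling
  k <- pixel_pitch / spacing
  if (abs(k - round(k)) > 1e-9)
    stop_invalid("'pixel_pitch' must be an integer multiple of the fine grid ",
                 "spacing p2/fine_sampling")
  fov_pixels <- as.integer(rep_len(fov_pixels, 2L))
  if (any(fov_pixels < 1)) stop_invalid("'fov_pixels' must be >= 1")
  structure(list(
    p1 = p1, p2 = p2, design_energy_keV = design_energy_keV,
    wavelength = wl, talbot_order = as.integer(talbot_order),
    distance_d = distance_d, pixel_pitch = pixel_pitch,
    fine_sampling = as.integer(fine_sampling),
    grid_spacing = spacing, samples_per_pixel = as.integer(round(k)),
    fov_pixels = fov_pixels, duty_g1 = duty_g1, duty_g2 = duty_g2,
    phase_shift = phase_shift, bar_transmission = bar_transmission,
    guard_periods = as.integer(guard_periods), source_sigma = source_sigma
  ), class = "gi_geometry")
}

#' @export
print.gi_geometry <- function(x, ...) {
  cat("Talbot interferometer geometry\n")
  cat(sprintf("  p1 = %.3f um, p2 = %.3f um, E = %.1f keV (lambda = %.4g nm)\n",
              x$p1 * 1e6, x$p2 * 1e6, x$design_energy_keV, x$wavelength * 1e9))
  cat(sprintf("  Talbot order m = %d, d = %.3f cm, d_auto = %.3f um\n",
              x$talbot_order, x$distance_d * 100,
              autocorrelation_length(x$wavelength, x$distance_d, x$p2) * 1e6))
  cat(sprintf("  pixel %.0f um, FOV %d x %d px, %d samples per p2 period\n",
              x$pixel_pitch * 1e6, x$fov_pixels[1], x$fov_pixels[2],
              x$fine_sampling))
  invisible(x)
}

# next FFT-friendly (2,3,5-smooth) even integer >= n
good_fft_size <- function(n) {
  n <- max(2L, as.integer(ceiling(n)))
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L && n %% 2L == 0L) return(n)
    n <- n + 1L
  }
}

# fine transverse grid covering the field of view plus guard bands.
# x = 0 is the left edge of the field of view.
fine_grid <- function(geom, ny = NULL) {
  k <- geom$samples_per_pixel
  nx_fov <- geom$fov_pixels[1] * k
  ny_fov <- if (is.null(ny)) geom$fov_pixels[2] * k else ny
  guard <- geom$guard_periods * geom$fine_sampling
  nx <- good_fft_size(nx_fov + 2L * guard)
  x_start <- (nx - nx_fov) %/% 2L  # samples before the FOV
  if (is.null(ny) && ny_fov > 1L) {
    nyg <- good_fft_size(ny_fov + 2L * guard)
    y_start <- (nyg - ny_fov) %/% 2L
  } else {
    nyg <- ny_fov
    y_start <- 0L
  }
  list(
    nx = nx, ny = nyg, spacing = geom$grid_spacing,
    x = (seq_len(nx) - 1L - x_start) * geom$grid_spacing,
    y = (seq_len(nyg) - 1L - y_start) * geom$grid_spacing,
    fov_ix = x_start + seq_len(nx_fov),
    fov_iy = y_start + seq_len(ny_fov),
    samples_per_pixel = k
  )
}
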