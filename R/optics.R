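#' Complex wavefield on the fine transverse grid
#'
#' A scalar complex amplitude sampled on the fine 2-D grid. The first matrix
#' dimension runs along x (the grating modulation direction), the second
#' along y.
#'
#' @param amplitude complex (or numeric) matrix.
#' @param grid_spacing sample pitch in metres.
#' @param x optional x coordinates of the rows (metres); defaults to
#'   `(0:(nx-1)) * grid_spacing`.
#' @return an object of class `wavefield`.
#' @export
wavefield <- function(amplitude, grid_spacing, x = NULL) {
  if (!is.matrix(amplitude)) amplitude <- matrix(amplitude, ncol = 1L)
  if (!all(is.finite(Re(amplitude))) || !all(is.finite(Im(amplitude))))
    stop_invalid("wavefield amplitude must be finite")
  if (is.null(x)) x <- (seq_len(nrow(amplitude)) - 1L) * grid_spacing
  structure(list(amplitude = as.matrix(amplitude) + 0i,
                 grid_spacing = grid_spacing, x = x),
            class = "wavefield")
}

#' @export
print.wavefield <- function(x, ...) {
  cat(sprintf("wavefield: %d x %d samples at %.4g um spacing\n",
              nrow(x$amplitude), ncol(x$amplitude), x$grid_spacing * 1e6))
  invisible(x)
}

# total integrated intensity (conserved by propagation)
field_energy <- function(field) sum(Mod(field$amplitude)^2)

# rectangular pulse train: 1 where the point falls in the open fraction of
# the period, 0 in the remainder. Phases are snapped to 1e-9 of a period so
# that edge samples are classified consistently under shifts of whole
# periods (floating-point modulo jitter).
pulse_train <- function(x, period, duty = 0.5, shift = 0) {
  ph <- (x - shift) / period
  ph <- ph - floor(ph)
  ph <- round(ph * 1e9) / 1e9
  ph[ph >= 1] <- 0
  as.numeric(ph < duty)
}

#' Apply the phase grating G1
#'
#' Multiplies the amplitude by `exp(i * phase_shift * Pi(x))` where `Pi` is
#' a rectangular pulse train of period `p1` along x. A pure phase element:
#' the magnitude map is unchanged.
#'
#' @param field a [wavefield()].
#' @param p1 grating pitch in metres.
#' @param duty_cycle open fraction of the period (default 0.5).
#' @param phase_shift phase advance in the shifted lamellae, radians
#'   (default `pi`).
#' @return a `wavefield`.
#' @export
apply_phase_grating <- function(field, p1, duty_cycle = 0.5, phase_shift = pi) {
  stopifnot(inherits(field, "wavefield"))
  g <- exp(1i * phase_shift * pulse_train(field$x, p1, duty_cycle))
  field$amplitude <- field$amplitude * g
  field
}

#' Free-space Fresnel propagation
#'
#' Angular-spectrum propagation over `distance`: the 2-D Fourier transform
#' of the amplitude is multiplied by
#' `H(u, v) = exp(-i * pi * distance * wavelength * (u^2 + v^2))` and
#' transformed back. Unitary on the periodic grid, so the total integrated
#' intensity is conserved.
#'
#' @param field a [wavefield()].
#' @param distance propagation distance in metres (>= 0).
#' @param wavelength wavelength in metres.
#' @return a `wavefield`.
#' @export
propagate <- function(field, distance, wavelength) {
  stopifnot(inherits(field, "wavefield"))
  if (distance < 0) stop_invalid("'distance' must be >= 0")
  if (distance == 0) return(field)
  a <- field$amplitude
  nx <- nrow(a)
  ny <- ncol(a)
  fx <- fft_freq(nx, field$grid_spacing)
  h <- exp(-1i * pi * distance * wavelength * fx^2)
  if (ny > 1L) {
    fy <- fft_freq(ny, field$grid_spacing)
    hy <- exp(-1i * pi * distance * wavelength * fy^2)
    a <- fft(fft(a) * outer(h, hy), inverse = TRUE) / length(a)
  } else {
    v <- fft(fft(a[, 1L]) * h, inverse = TRUE) / nx
    a <- matrix(v, ncol = 1L)
  }
  field$amplitude <- a
  field
}

# DFT sample frequencies (cycles per metre)
fft_freq <- function(n, spacing) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq_len(floor(n / 2)) - floor(n / 2) - 1L)
  k / (n * spacing)
}

#' Gaussian source (G0 aperture) blur of the complex amplitude
#'
#' Convolves the complex amplitude with a Gaussian of standard deviation
#' `aperture_sigma` (Fourier-domain multiplication by
#' `exp(-2*pi^2*sigma^2*(u^2+v^2))`). Width 0 is the identity. Acting on
#' the amplitude (not the intensity), the visibility of a pure sinusoid of
#' period p is damped by `exp(-2*pi^2*sigma^2/p^2)`.
#'
#' @param field a [wavefield()].
#' @param aperture_sigma Gaussian standard deviation in metres (>= 0).
#' @return a `wavefield`.
#' @export
apply_source_blur <- function(field, aperture_sigma) {
  stopifnot(inherits(field, "wavefield"))
  if (aperture_sigma < 0) stop_invalid("'aperture_sigma' must be >= 0")
  if (aperture_sigma == 0) return(field)
  a <- field$amplitude
  nx <- nrow(a)
  ny <- ncol(a)
  fx <- fft_freq(nx, field$grid_spacing)
  gx <- exp(-2 * pi^2 * aperture_sigma^2 * fx^2)
  if (ny > 1L) {
    fy <- fft_freq(ny, field$grid_spacing)
    g <- outer(gx, exp(-2 * pi^2 * aperture_sigma^2 * fy^2))
    a <- fft(fft(a) * g, inverse = TRUE) / length(a)
  } else {
    a <- matrix(fft(fft(a[, 1L]) * gx, inverse = TRUE) / nx, ncol = 1L)
  }
  field$amplitude <- a
  field
}

#' Apply the analyzer (absorption) grating G2 and detect intensity
#'
#' Multiplies the intensity `|psi|^2` by a shifted rectangular transmission
#' train along x: open slits transmit 1, bars transmit `bar_transmission`
#' (default 0, ideal absorber). `step_position` shifts the train, as in
#' phase stepping.
#'
#' @param field a [wavefield()].
#' @param p2 analyzer pitch in metres.
#' @param step_position grating offset x_G2 in metres.
#' @param duty_cycle open fraction (default 0.5).
#' @param bar_transmission intensity transmission of the bars in `[0, 1]`.
#' @return intensity matrix (same dimensions as the amplitude).
#' @export
apply_analyzer_grating <- function(field, p2, step_position = 0,
                                   duty_cycle = 0.5, bar_transmission = 0) {
  stopifnot(inherits(field, "wavefield"))
  if (bar_transmission < 0 || bar_transmission > 1)
    stop_invalid("'bar_transmission' must lie in [0, 1]")
  open <- pulse_train(field$x, p2, duty_cycle, shift = step_position)
  trans <- open + bar_transmission * (1 - open)
  Mod(field$amplitude)^2 * trans
}
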