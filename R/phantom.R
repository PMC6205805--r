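#' Nominal sphere count per pixel column
#'
#' Number of alveolar spheres whose summed volume fills a fraction
#' `volume_fraction` of the column `pixel_area * slab_thickness`:
#' `round(f * A * t / ((4/3) * pi * (S/2)^3))`. Because sphere overlap is
#' permitted, this is a nominal (sum-of-volumes) target; the realized union
#' air fraction of a dense pack is lower.
#'
#' @param pixel_area transverse area in m^2.
#' @param slab_thickness slab thickness t in metres.
#' @param diameter sphere diameter S in metres.
#' @param volume_fraction nominal volume fraction f, in (0, 1).
#' @return integer sphere count.
#' @examples
#' plan_sphere_count(100e-6^2, 1.8e-3, 39e-6, 0.56) # 325
#' @export
plan_sphere_count <- function(pixel_area, slab_thickness, diameter,
                              volume_fraction) {
  if (any(c(pixel_area, slab_thickness, diameter) <= 0))
    stop_invalid("'pixel_area', 'slab_thickness' and 'diameter' must be > 0")
  if (volume_fraction < 0 || volume_fraction >= 1)
    stop_invalid("'volume_fraction' must lie in [0, 1)")
  v_sphere <- (4 / 3) * pi * (diameter / 2)^3
  as.integer(round(volume_fraction * pixel_area * slab_thickness / v_sphere))
}

#' Generate a random overlapping-sphere lung slab
#'
#' Draws sphere centres uniformly at random over
#' `lateral_extent x lateral_extent x [0, slab_thickness]`; sphere volumes
#' may overlap (monodisperse, zero wall thickness). The count is the nominal
#' sum-of-volumes count [plan_sphere_count()] scaled to the lateral extent.
#' Centres are drawn in a fixed coordinate frame with the lateral extent
#' centred on `centre`.
#'
#' @param geometry a [gi_geometry()]; used to size the lateral extent as the
#'   optical grid plus one sphere diameter of margin per side, unless
#'   `lateral_extent` is given.
#' @param diameter sphere diameter S in metres.
#' @param slab_thickness slab thickness t in metres.
#' @param volume_fraction nominal volume fraction (default 0.56).
#' @param seed integer RNG seed; identical seeds give identical packs.
#' @param lateral_extent optional explicit lateral extent (metres, one side
#'   of the square footprint).
#' @param centre transverse centre (x, y) of the footprint in metres.
#' @return an object of class `sphere_pack` with fields `centers` (n x 3
#'   matrix, columns x/y/z in metres), `diameter`, `slab_thickness`,
#'   `lateral_extent`, `nominal_volume_fraction`, `seed`.
#' @export
generate_sphere_pack <- function(geometry = NULL, diameter, slab_thickness,
                                 volume_fraction = 0.56, seed = 1L,
                                 lateral_extent = NULL, centre = c(0, 0)) {
  if (diameter <= 0 || slab_thickness <= 0)
    stop_invalid("'diameter' and 'slab_thickness' must be > 0")
  if (is.null(lateral_extent)) {
    if (is.null(geometry))
      stop_invalid("either 'geometry' or 'lateral_extent' must be given")
    g <- fine_grid(geometry)
    lateral_extent <- max(g$nx, g$ny) * g$spacing + 2 * diameter
    centre <- c(mean(range(g$x)) + g$spacing / 2,
                mean(range(g$y)) + g$spacing / 2)
  }
  n <- plan_sphere_count(lateral_extent^2, slab_thickness, diameter,
                         volume_fraction)
  centers <- with_seed(seed, {
    cbind(
      x = runif(n, centre[1] - lateral_extent / 2, centre[1] + lateral_extent / 2),
      y = runif(n, centre[2] - lateral_extent / 2, centre[2] + lateral_extent / 2),
      z = runif(n, 0, slab_thickness)
    )
  })
  structure(list(
    centers = centers, diameter = diameter, slab_thickness = slab_thickness,
    lateral_extent = lateral_extent, nominal_volume_fraction = volume_fraction,
    seed = as.integer(seed), centre = centre
  ), class = "sphere_pack")
}

#' @export
print.sphere_pack <- function(x, ...) {
  cat(sprintf(paste0(
    "sphere_pack: %d spheres of diameter %.0f um in a %.2f mm slab\n",
    "  lateral extent %.2f mm, nominal volume fraction %.2f, seed %d\n"),
    nrow(x$centers), x$diameter * 1e6, x$slab_thickness * 1e3,
    x$lateral_extent * 1e3, x$nominal_volume_fraction, x$seed))
  invisible(x)
}

#' Project a sphere pack to per-ray air path lengths
#'
#' For every transverse fine-grid sample, computes the chord interval of
#' each sphere intersecting the ray, clipped to the slab `[0, t]`, and
#' combines the chords along z with one of two overlap semantics:
#'
#' * `overlap = "union"` — overlapping intervals are merged before summing:
#'   the exact geometric union air path, never exceeding `t`;
#' * `overlap = "sum"` — each sphere's chord is added independently, so
#'   regions covered by several spheres are counted once per sphere. This
#'   is the semantics under which a dense overlapping pack projects like a
#'   non-overlapping pack of the same nominal volume fraction, and it is
#'   the mode used by the lung modelling presets.
#'
#' @param pack a [generate_sphere_pack()] result.
#' @param x,y fine grid sample coordinates in metres (vectors). Either give
#'   these or `geometry`.
#' @param geometry optional [gi_geometry()] whose fine grid supplies `x`/`y`.
#' @param overlap `"union"` or `"sum"` (see above).
#' @return an object of class `projected_object`: list with `air_path`
#'   (length(x) x length(y) matrix, metres), `grid_spacing`,
#'   `slab_thickness`, `overlap`.
#' @export
project_air_path <- function(pack, geometry = NULL, x = NULL, y = NULL,
                             overlap = c("union", "sum")) {
  overlap <- match.arg(overlap)
  if (!inherits(pack, "sphere_pack")) stop_invalid("'pack' must be a sphere_pack")
  if (is.null(x) || is.null(y)) {
    if (is.null(geometry)) stop_invalid("give either 'geometry' or 'x' and 'y'")
    g <- fine_grid(geometry)
    x <- g$x
    y <- g$y
    spacing <- g$spacing
  } else {
    spacing <- if (length(x) > 1L) x[2] - x[1] else diff(range(y)) / max(1L, length(y) - 1L)
  }
  n <- nrow(pack$centers)
  if (n == 0L) {
    ap <- matrix(0, length(x), length(y))
  } else {
    dx <- if (length(x) > 1L) x[2] - x[1] else 1
    dy <- if (length(y) > 1L) y[2] - y[1] else 1
    ap <- project_air_path_cpp(pack$centers[, 1], pack$centers[, 2],
                               pack$centers[, 3], pack$diameter / 2,
                               pack$slab_thickness,
                               x[1], dx, length(x), y[1], dy, length(y),
                               merge_overlaps = (overlap == "union"))
  }
  structure(list(air_path = ap, grid_spacing = spacing,
                 slab_thickness = pack$slab_thickness, overlap = overlap),
            class = "projected_object")
}

#' Complex transmission of a projected slab
#'
#' Projection-approximation transmission of the slab: each ray crosses
#' `air_path` of air and `t - air_path` of tissue, giving
#' `O = exp(i*(2*pi/lambda)*(delta_air*a + delta_tis*(t-a))
#'         - (2*pi/lambda)*(beta_air*a + beta_tis*(t-a)))`.
#' `|O| <= 1` whenever both betas are nonnegative. For a `"sum"`-overlap
#' projection the air path may locally exceed `t`; the (linear) exponent is
#' simply extrapolated, consistent with each sphere contributing its full
#' chord. For a `"union"` projection `air_path > t` indicates an internal
#' inconsistency and is an error.
#'
#' @param projected a [project_air_path()] result.
#' @param tissue,air [material_optics()] of the two phases.
#' @param wavelength wavelength in metres.
#' @return complex matrix with the dimensions of `projected$air_path`.
#' @export
object_transmission <- function(projected, tissue, air, wavelength) {
  if (!inherits(projected, "projected_object"))
    stop_invalid("'projected' must be a projected_object")
  t <- projected$slab_thickness
  if (t < 0) stop_invalid("slab thickness must be >= 0")
  a <- projected$air_path
  if (!identical(projected$overlap, "sum") &&
      any(a > t + 1e-12 * max(t, 1)))
    stop_invalid("air path exceeds slab thickness: inconsistent projection")
  tis <- t - a
  k <- 2 * pi / wavelength
  phase <- k * (air$delta * a + tissue$delta * tis)
  atten <- k * (air$beta * a + tissue$beta * tis)
  exp(-atten + 1i * phase)  # keeps matrix dimensions
}

#' Write / read a sphere pack as plain CSV
#'
#' The header records diameter, slab thickness, lateral extent, nominal
#' volume fraction and seed as commented key=value lines, so a pack can be
#' re-used bit-identically across runs.
#'
#' @param pack a `sphere_pack`.
#' @param path file path.
#' @return `read_sphere_pack` returns a `sphere_pack`.
#' @export
write_sphere_pack <- function(pack, path) {
  hdr <- sprintf("# %s=%.17g",
                 c("diameter", "slab_thickness", "lateral_extent",
                   "nominal_volume_fraction", "seed"),
                 c(pack$diameter, pack$slab_thickness, pack$lateral_extent,
                   pack$nominal_volume_fraction, pack$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.csv(as.data.frame(pack$centers), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sphere_pack
#' @export
read_sphere_pack <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# *", "", hdr), "="))
  vals <- setNames(as.numeric(kv[, 2]), kv[, 1])
  centers <- as.matrix(read.csv(text = lines[!grepl("^#", lines)]))
  structure(list(
    centers = centers, diameter = vals[["diameter"]],
    slab_thickness = vals[["slab_thickness"]],
    lateral_extent = vals[["lateral_extent"]],
    nominal_volume_fraction = vals[["nominal_volume_fraction"]],
    seed = as.integer(vals[["seed"]]), centre = c(0, 0)
  ), class = "sphere_pack")
}
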