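#' Dark-field thickness series
#'
#' For each slab thickness and repetition, generates a fresh sphere pack
#' (seed = `base_seed` + repetition index), acquires object and reference
#' phase-stepping stacks, retrieves the dark-field image and averages it
#' over the field of view. The reference stack is computed once per
#' geometry and reused.
#'
#' @param config a [load_preset()] run configuration (or a compatible list
#'   with `geometry`, `materials`, `phantom` and `detector` entries).
#' @param sphere_diameter sphere diameter in metres; defaults to the
#'   configuration's default diameter.
#' @param thicknesses slab thicknesses in metres; defaults to the
#'   configuration's thickness list.
#' @param n_repetitions repetitions per thickness (>= 1); defaults to the
#'   configuration's value.
#' @param base_seed integer; repetition r uses seed `base_seed + r - 1`.
#' @param n_steps phase steps per stack (default 8).
#' @param verbose print progress?
#' @return an object of class `df_series`: list with a `data` data frame
#'   (`thickness`, `mean_df`, `sd_df`, `n`), `sphere_diameter`,
#'   `preset_name`, `geometry`, `n_repetitions`, `base_seed`.
#' @export
run_thickness_series <- function(config, sphere_diameter = NULL,
                                 thicknesses = NULL, n_repetitions = NULL,
                                 base_seed = 1L, n_steps = 8L,
                                 verbose = FALSE) {
  geom <- config$geometry
  stopifnot(inherits(geom, "gi_geometry"))
  if (is.null(sphere_diameter)) sphere_diameter <- config$phantom$diameter
  if (is.null(thicknesses)) thicknesses <- config$phantom$thicknesses
  if (is.null(n_repetitions)) n_repetitions <- config$n_repetitions
  if (length(thicknesses) == 0L) stop_invalid("'thicknesses' must be nonempty")
  if (n_repetitions < 1L) stop_invalid("'n_repetitions' must be >= 1")
  detector <- config$detector
  if (is.null(detector)) detector <- detector_model(geom$pixel_pitch)
  vf <- config$phantom$volume_fraction
  if (is.null(vf)) vf <- 0.56
  overlap <- config$phantom$overlap
  if (is.null(overlap)) overlap <- "sum"

  ref <- acquire_stack(geom, phantom = NULL, detector = detector,
                       n_steps = n_steps, seed = base_seed)
  rows <- lapply(seq_along(thicknesses), function(it) {
    t <- thicknesses[it]
    dfs <- vapply(seq_len(n_repetitions), function(r) {
      seed <- base_seed + (r - 1L)
      pack <- generate_sphere_pack(geom, diameter = sphere_diameter,
                                   slab_thickness = t,
                                   volume_fraction = vf, seed = seed)
      obj <- acquire_stack(geom, phantom = pack, detector = detector,
                           materials = config$materials, n_steps = n_steps,
                           seed = seed + 1000L, overlap = overlap)
      gi <- compute_gi_images(obj, ref)
      mean(gi$dark_field)
    }, numeric(1))
    if (verbose)
      message(sprintf("  t = %.2f mm: mean df = %.4f (sd %.2g, n = %d)",
                      t * 1e3, mean(dfs), sd(dfs), n_repetitions))
    data.frame(thickness = t, mean_df = mean(dfs),
               sd_df = if (n_repetitions > 1L) sd(dfs) else NA_real_,
               n = n_repetitions)
  })
  structure(list(
    data = do.call(rbind, rows), sphere_diameter = sphere_diameter,
    preset_name = if (is.null(config$preset_name)) "custom" else config$preset_name,
    geometry = geom, n_repetitions = n_repetitions,
    base_seed = as.integer(base_seed)
  ), class = "df_series")
}

#' @export
print.df_series <- function(x, ...) {
  cat(sprintf("Dark-field thickness series (%s, S = %.0f um, %d repetitions)\n",
              x$preset_name, x$sphere_diameter * 1e6, x$n_repetitions))
  d <- x$data
  print(data.frame(thickness_mm = d$thickness * 1e3,
                   mean_df = round(d$mean_df, 4),
                   sd_df = signif(d$sd_df, 3)), row.names = FALSE)
  invisible(x)
}

# geometric prefactor of the diffusion law, 2*pi^2*d^2/p2^2 (dimensionless)
slope_factor <- function(geometry) {
  2 * pi^2 * (geometry$distance_d / geometry$p2)^2
}

#' Fit the linear diffusion coefficient
#'
#' Fits the diffusion law `-log(df) = (2*pi^2*d^2/p2^2) * epsilon * t` to a
#' dark-field thickness series by least squares through the origin
#' (the law forces `-log(df) = 0` at `t = 0`), with inverse-variance
#' weights from the repetition standard deviations when available. A
#' free-intercept fit is kept as a diagnostic.
#'
#' @param series a [run_thickness_series()] result, or a data frame with
#'   columns `thickness` (m), `mean_df` and optionally `sd_df`.
#' @param geometry a [gi_geometry()]; defaults to the series' geometry.
#' @return an object of class `epsilon_fit` with components `epsilon`
#'   (1/mm), `epsilon_se` (1/mm), `r_squared`, `slope_factor`, the
#'   underlying `lm` fits and the series.
#' @examples
#' geom <- gi_geometry(fov_pixels = c(2, 2))
#' t <- seq(1.8e-3, 10.8e-3, by = 1.8e-3)
#' df <- predict_df(1.31e-11, t, geom)
#' fit <- fit_epsilon(data.frame(thickness = t, mean_df = df), geom)
#' coef(fit) # 1.31e-11, recovered exactly
#' @export
fit_epsilon <- function(series, geometry = NULL) {
  if (inherits(series, "df_series")) {
    if (is.null(geometry)) geometry <- series$geometry
    dat <- series$data
  } else {
    dat <- as.data.frame(series)
  }
  if (is.null(geometry)) stop_invalid("'geometry' is required")
  if (nrow(dat) < 2L) stop_invalid("at least two thicknesses are required")
  if (any(dat$mean_df <= 0))
    stop_invalid("dark-field signal saturated (mean_df <= 0): cannot take log")
  if (any(dat$mean_df > 1 + 1e-6))
    warning("mean_df above 1; fit proceeds on -log(df)")
  t_mm <- dat$thickness * 1e3
  y <- -log(dat$mean_df)
  w <- NULL
  if (!is.null(dat$sd_df) && all(is.finite(dat$sd_df)) && all(dat$sd_df > 0))
    w <- 1 / dat$sd_df^2
  fit0 <- lm(y ~ 0 + t_mm, weights = w)
  fit1 <- lm(y ~ t_mm, weights = w)
  k <- slope_factor(geometry)
  slope <- unname(coef(fit0)[["t_mm"]])
  # suppress the "essentially perfect fit" warning for noiseless series
  s0 <- suppressWarnings(summary(fit0))
  se <- unname(s0$coefficients[1, 2])
  structure(list(
    epsilon = slope / k, epsilon_se = se / k,
    r_squared = s0$r.squared, slope_factor = k,
    fit_origin = fit0, fit_intercept = fit1,
    series = if (inherits(series, "df_series")) series else
      structure(list(data = dat, geometry = geometry,
                     sphere_diameter = NA_real_, preset_name = "custom",
                     n_repetitions = if (is.null(dat$n)) 1L else max(dat$n),
                     base_seed = NA_integer_), class = "df_series"),
    geometry = geometry
  ), class = "epsilon_fit")
}

#' @export
print.epsilon_fit <- function(x, digits = 3, ...) {
  cat("Linear diffusion coefficient fit, -log(df) = 2*pi^2*d^2/p2^2 * eps * t\n")
  cat(sprintf("  epsilon = %.*g +/- %.*g 1/mm   (r^2 = %.4f, n = %d thicknesses)\n",
              digits, x$epsilon, digits, x$epsilon_se, x$r_squared,
              nrow(x$series$data)))
  invisible(x)
}

#' @export
coef.epsilon_fit <- function(object, ...) {
  c(epsilon = object$epsilon)
}

#' @export
summary.epsilon_fit <- function(object, ...) {
  ci <- confint(object)
  int <- coef(object$fit_intercept)
  structure(list(
    epsilon = object$epsilon, epsilon_se = object$epsilon_se,
    conf_int = ci, r_squared = object$r_squared,
    slope_factor = object$slope_factor,
    intercept_diagnostic = unname(int[1]),
    epsilon_free_intercept = unname(int[2]) / object$slope_factor,
    series = object$series
  ), class = "summary.epsilon_fit")
}

#' @export
print.summary.epsilon_fit <- function(x, ...) {
  cat("Linear diffusion coefficient fit (zero-intercept weighted LS)\n")
  cat(sprintf("  epsilon      = %.4g 1/mm  (se %.2g; 95%% CI %.4g .. %.4g)\n",
              x$epsilon, x$epsilon_se, x$conf_int[1], x$conf_int[2]))
  cat(sprintf("  r^2          = %.5f\n", x$r_squared))
  cat(sprintf("  slope factor = %.4g (2*pi^2*d^2/p2^2)\n", x$slope_factor))
  cat(sprintf("  free-intercept diagnostic: intercept %.3g, epsilon %.4g 1/mm\n",
              x$intercept_diagnostic, x$epsilon_free_intercept))
  invisible(x)
}

#' @export
confint.epsilon_fit <- function(object, parm = "epsilon", level = 0.95, ...) {
  df <- object$fit_origin$df.residual
  q <- qt(1 - (1 - level) / 2, df)
  c(object$epsilon - q * object$epsilon_se,
    object$epsilon + q * object$epsilon_se)
}

#' @export
predict.epsilon_fit <- function(object, thickness = NULL, ...) {
  if (is.null(thickness)) thickness <- object$series$data$thickness
  predict_df(object$epsilon, thickness, object$geometry)
}

#' @export
residuals.epsilon_fit <- function(object, ...) {
  object$series$data$mean_df - predict(object)
}

#' @export
plot.epsilon_fit <- function(x, ...) {
  d <- x$series$data
  t_mm <- d$thickness * 1e3
  plot(t_mm, -log(d$mean_df), xlab = "thickness t [mm]",
       ylab = "-log(df)", pch = 19,
       main = sprintf("epsilon = %.3g 1/mm", x$epsilon), ...)
  tt <- seq(0, max(t_mm), length.out = 100)
  lines(tt, x$slope_factor * x$epsilon * tt)
  invisible(x)
}

#' Predict the dark-field signal from the diffusion law
#'
#' `df = exp(-(2*pi^2*d^2/p2^2) * epsilon * t)` with `epsilon` in 1/mm and
#' `t` in metres.
#'
#' @param epsilon linear diffusion coefficient in 1/mm (>= 0).
#' @param thickness slab thickness in metres (>= 0, vectorized).
#' @param geometry a [gi_geometry()].
#' @return dark-field signal in (0, 1].
#' @export
predict_df <- function(epsilon, thickness, geometry) {
  if (any(epsilon < 0)) stop_invalid("'epsilon' must be >= 0")
  if (any(thickness < 0)) stop_invalid("'thickness' must be >= 0")
  exp(-slope_factor(geometry) * epsilon * thickness * 1e3)
}

#' Invert the diffusion law for a single ROI measurement
#'
#' Single-point inversion: `epsilon = -log(df) / ((2*pi^2*d^2/p2^2) * t)`,
#' relating one measured dark-field value and the local tissue thickness.
#'
#' @param df_value measured dark-field signal, in (0, 1].
#' @param thickness local thickness in metres (> 0).
#' @param geometry a [gi_geometry()].
#' @return epsilon in 1/mm.
#' @export
epsilon_from_roi <- function(df_value, thickness, geometry) {
  if (any(df_value <= 0) || any(df_value > 1))
    stop_invalid("'df_value' must lie in (0, 1]")
  if (any(thickness <= 0)) stop_invalid("'thickness' must be > 0")
  -log(df_value) / (slope_factor(geometry) * thickness * 1e3)
}

#' Compare murine and human dark-field responses
#'
#' Reports the epsilon ratio, the simulated dark field at each model's
#' maximum thickness, and a relative-thickness table (df versus t/t_max in
#' steps of 1/6) for plotting the two responses on a common axis.
#'
#' @param murine_fit,human_fit [fit_epsilon()] results.
#' @param murine_series,human_series the corresponding
#'   [run_thickness_series()] results.
#' @return an object of class `df_comparison`.
#' @export
murine_human_comparison <- function(murine_fit, human_fit,
                                    murine_series, human_series) {
  stopifnot(inherits(murine_fit, "epsilon_fit"),
            inherits(human_fit, "epsilon_fit"))
  md <- murine_series$data
  hd <- human_series$data
  rel <- data.frame(
    relative_thickness = md$thickness / max(md$thickness),
    murine_df = md$mean_df,
    human_df = hd$mean_df[order(hd$thickness)][seq_len(nrow(md))]
  )
  structure(list(
    epsilon_ratio = murine_fit$epsilon / human_fit$epsilon,
    murine_epsilon = murine_fit$epsilon, human_epsilon = human_fit$epsilon,
    murine_df_at_tmax = md$mean_df[which.max(md$thickness)],
    human_df_at_tmax = hd$mean_df[which.max(hd$thickness)],
    relative_thickness_table = rel
  ), class = "df_comparison")
}

#' @export
print.df_comparison <- function(x, ...) {
  cat("Murine vs human dark-field comparison\n")
  cat(sprintf("  epsilon murine = %.4g 1/mm, human = %.4g 1/mm, ratio = %.1f\n",
              x$murine_epsilon, x$human_epsilon, x$epsilon_ratio))
  cat(sprintf("  df at maximum thickness: murine %.3f, human %.3f\n",
              x$murine_df_at_tmax, x$human_df_at_tmax))
  invisible(x)
}
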