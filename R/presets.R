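#' Load a study preset
#'
#' Returns a fully resolved run configuration for the murine or human lung
#' modelling study: interferometer geometry, air/muscle optical constants
#' at the design energy, phantom parameters (alveolar diameters, thickness
#' list, nominal volume fraction) and an ideal detector.
#'
#' Presets:
#' * `"murine"` — alveolar diameters 39/60/80 um (default 60; the smallest
#'   diameter is also reported as 40 um in places, the preset uses 39),
#'   pixel 100 um, mean energy 27.7 keV, first Talbot distance
#'   (~4.47 cm), thicknesses 1.8 .. 10.8 mm, field of view 5 x 5 pixels.
#' * `"human"` — alveolar diameters 200/300/400 um (default 300), pixel
#'   150 um, mean energy 64.5 keV, first Talbot distance (~10.4 cm),
#'   thicknesses 25 .. 150 mm, field of view 10 x 10 pixels.
#'
#' @param name `"murine"` or `"human"`.
#' @param diameter sphere diameter override in metres (must be one of the
#'   preset's diameters or any positive length).
#' @param fov_pixels field-of-view override, length-2 integer.
#' @param fine_sampling fine samples per p2 period (default 16).
#' @param n_repetitions repetitions per thickness (default 10).
#' @param noise enable detector noise? (default FALSE; the studies use a
#'   high exposure of 1e3 mGy precisely so that noise is negligible).
#' @param eak entrance air kerma in mGy (default 1e3).
#' @param mtf_file,nps_file optional measured-curve files
#'   ([read_frequency_curve()]).
#' @param ... further overrides passed to [gi_geometry()].
#' @return an object of class `run_configuration`.
#' @examples
#' cfg <- load_preset("murine")
#' cfg$geometry$pixel_pitch # 1e-4 m
#' @export
load_preset <- function(name, diameter = NULL, fov_pixels = NULL,
                        fine_sampling = 16L, n_repetitions = 10L,
                        noise = FALSE, eak = 1e3, mtf_file = NULL,
                        nps_file = NULL, ...) {
  presets <- c("murine", "human")
  if (!is.character(name) || length(name) != 1L || !(name %in% presets))
    stop_invalid("unknown preset '", paste(name, collapse = ","),
                 "'; available presets: ", paste(presets, collapse = ", "))
  if (name == "murine") {
    energy <- 27.7
    pixel <- 100e-6
    fov <- c(5L, 5L)
    diameters <- c(39e-6, 60e-6, 80e-6)
    thicknesses <- seq(1.8e-3, 10.8e-3, by = 1.8e-3)
  } else {
    energy <- 64.5
    pixel <- 150e-6
    fov <- c(10L, 10L)
    diameters <- c(200e-6, 300e-6, 400e-6)
    thicknesses <- seq(25e-3, 150e-3, by = 25e-3)
  }
  if (!is.null(fov_pixels)) fov <- as.integer(rep_len(fov_pixels, 2L))
  geom <- gi_geometry(design_energy_keV = energy, pixel_pitch = pixel,
                      fine_sampling = fine_sampling, fov_pixels = fov, ...)
  mats <- .material_table[[name]]
  materials <- list(
    air = material_optics(mats$air[["delta"]], mats$air[["beta"]],
                          sprintf("air @ %.1f keV", energy)),
    muscle = material_optics(mats$muscle[["delta"]], mats$muscle[["beta"]],
                             sprintf("muscle @ %.1f keV", energy)))
  materials$tissue <- materials$muscle
  det <- detector_model(
    pixel_pitch = pixel,
    mtf_curve = if (!is.null(mtf_file)) read_frequency_curve(mtf_file, TRUE),
    nps_curve = if (!is.null(nps_file)) read_frequency_curve(nps_file),
    noise = noise, eak = eak)
  if (is.null(diameter)) diameter <- diameters[2]
  structure(list(
    preset_name = name, geometry = geom, materials = materials,
    detector = det,
    phantom = list(diameter = diameter, diameters = diameters,
                   thicknesses = thicknesses, volume_fraction = 0.56,
                   overlap = "sum"),
    n_repetitions = as.integer(n_repetitions)
  ), class = "run_configuration")
}

#' @export
print.run_configuration <- function(x, ...) {
  cat(sprintf("run_configuration: preset '%s'\n", x$preset_name))
  print(x$geometry)
  cat(sprintf("  phantom: S = %.0f um (of %s), f = %.2f, t = %s mm, %d reps\n",
              x$phantom$diameter * 1e6,
              paste(x$phantom$diameters * 1e6, collapse = "/"),
              x$phantom$volume_fraction,
              paste(signif(x$phantom$thicknesses * 1e3, 4), collapse = ", "),
              x$n_repetitions))
  print(x$detector)
  invisible(x)
}

#' Desk-scale reduction of a run configuration
#'
#' Jointly reduces the field of view, the fine sampling and the number of
#' repetitions for quick runs. This changes only the stochastic precision
#' of the estimates (fewer pixels and repetitions to average over), not the
#' estimand: the diffusion law and its prefactor are untouched.
#'
#' @param config a [load_preset()] result.
#' @param fov_pixels reduced field of view (default 2 x 2).
#' @param fine_sampling reduced fine sampling (default 12 samples per p2).
#' @param n_repetitions reduced repetition count (default 3).
#' @return the reduced `run_configuration`.
#' @export
scale_configuration <- function(config, fov_pixels = c(2L, 2L),
                                fine_sampling = 12L, n_repetitions = 3L) {
  stopifnot(inherits(config, "run_configuration"))
  load_preset(config$preset_name, diameter = config$phantom$diameter,
              fov_pixels = fov_pixels, fine_sampling = fine_sampling,
              n_repetitions = n_repetitions,
              noise = config$detector$noise, eak = config$detector$eak)
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [load_preset()] (`preset`, `diameter_um`,
#' `fov_pixels`, `fine_sampling`, `n_repetitions`, `noise`, `eak`,
#' `mtf_file`, `nps_file`) plus optional `thicknesses_mm` and `base_seed`.
#'
#' @param path YAML file path.
#' @return a `run_configuration` with `base_seed` and possibly overridden
#'   thicknesses attached.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$preset)) stop_invalid("config file must name a 'preset'")
  cfg <- load_preset(
    y$preset,
    diameter = if (!is.null(y$diameter_um)) y$diameter_um * 1e-6,
    fov_pixels = y$fov_pixels,
    fine_sampling = if (is.null(y$fine_sampling)) 16L else y$fine_sampling,
    n_repetitions = if (is.null(y$n_repetitions)) 10L else y$n_repetitions,
    noise = isTRUE(y$noise),
    eak = if (is.null(y$eak)) 1e3 else y$eak,
    mtf_file = y$mtf_file, nps_file = y$nps_file)
  if (!is.null(y$thicknesses_mm))
    cfg$phantom$thicknesses <- as.numeric(y$thicknesses_mm) * 1e-3
  cfg$base_seed <- if (is.null(y$base_seed)) 1L else as.integer(y$base_seed)
  cfg
}

# serialize the resolved configuration as commented header lines, so every
# output file carries the parameters needed to re-run it
config_header <- function(config, base_seed, n_steps) {
  g <- config$geometry
  c(sprintf("# darkfieldsim %s", as.character(utils::packageVersion("darkfieldsim"))),
    sprintf("# preset=%s", config$preset_name),
    sprintf("# p1_um=%.4f p2_um=%.4f energy_keV=%.2f talbot_order=%d",
            g$p1 * 1e6, g$p2 * 1e6, g$design_energy_keV, g$talbot_order),
    sprintf("# d_cm=%.5f pixel_um=%.1f fine_sampling=%d fov=%dx%d",
            g$distance_d * 100, g$pixel_pitch * 1e6, g$fine_sampling,
            g$fov_pixels[1], g$fov_pixels[2]),
    sprintf("# diameter_um=%.1f volume_fraction=%.3f",
            config$phantom$diameter * 1e6, config$phantom$volume_fraction),
    sprintf("# delta_air=%.4g beta_air=%.4g delta_tissue=%.4g beta_tissue=%.4g",
            config$materials$air$delta, config$materials$air$beta,
            config$materials$tissue$delta, config$materials$tissue$beta),
    sprintf("# n_repetitions=%d base_seed=%d n_steps=%d noise=%s eak_mGy=%g",
            config$n_repetitions, base_seed, n_steps,
            config$detector$noise, config$detector$eak))
}

#' Run a thickness-series experiment and write its outputs
#'
#' Executes [run_thickness_series()] followed by [fit_epsilon()] and writes
#' a CSV (one row per thickness plus a summary row) whose commented header
#' records the full resolved configuration and seeds, sufficient to re-run
#' the experiment bit-identically.
#'
#' @param config a [load_preset()] / [read_run_config()] configuration.
#' @param out_dir output directory (created if needed).
#' @param base_seed integer base seed (default: `config$base_seed` or 1).
#' @param n_steps phase steps (default 8).
#' @param verbose print progress?
#' @return invisibly, a list with the `df_series`, the `epsilon_fit` and
#'   the path written.
#' @export
run_experiment <- function(config, out_dir, base_seed = NULL, n_steps = 8L,
                           verbose = TRUE) {
  stopifnot(inherits(config, "run_configuration"))
  if (is.null(base_seed))
    base_seed <- if (is.null(config$base_seed)) 1L else config$base_seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  series <- run_thickness_series(config, base_seed = base_seed,
                                 n_steps = n_steps, verbose = verbose)
  fit <- fit_epsilon(series)
  path <- file.path(out_dir, sprintf("%s_S%.0fum_series.csv",
                                     config$preset_name,
                                     config$phantom$diameter * 1e6))
  hdr <- c(config_header(config, base_seed, n_steps),
           sprintf("# epsilon_per_mm=%.6g epsilon_se_per_mm=%.3g r_squared=%.6f",
                   fit$epsilon, fit$epsilon_se, fit$r_squared))
  out <- series$data
  out$thickness_mm <- out$thickness * 1e3
  out$thickness <- NULL
  con <- file(path, "w")
  writeLines(hdr, con)
  write.csv(out[c("thickness_mm", "mean_df", "sd_df", "n")], con,
            row.names = FALSE)
  close(con)
  if (verbose) print(fit)
  invisible(list(series = series, fit = fit, path = path))
}

#' Run murine and human experiments and write their comparison
#'
#' Runs [run_experiment()] for both presets (at their configured diameters)
#' and writes an epsilon-ratio / relative-thickness comparison CSV.
#'
#' @param murine_config,human_config configurations from [load_preset()].
#' @param out_dir output directory.
#' @param base_seed,n_steps,verbose as in [run_experiment()].
#' @return invisibly, a list with both results and the `df_comparison`.
#' @export
run_comparison <- function(murine_config, human_config, out_dir,
                           base_seed = 1L, n_steps = 8L, verbose = TRUE) {
  rm_ <- run_experiment(murine_config, out_dir, base_seed, n_steps, verbose)
  rh <- run_experiment(human_config, out_dir, base_seed, n_steps, verbose)
  cmp <- murine_human_comparison(rm_$fit, rh$fit, rm_$series, rh$series)
  path <- file.path(out_dir, "murine_human_comparison.csv")
  con <- file(path, "w")
  writeLines(c(sprintf("# epsilon_murine_per_mm=%.6g", cmp$murine_epsilon),
               sprintf("# epsilon_human_per_mm=%.6g", cmp$human_epsilon),
               sprintf("# epsilon_ratio=%.4f", cmp$epsilon_ratio),
               sprintf("# murine_df_at_tmax=%.5f human_df_at_tmax=%.5f",
                       cmp$murine_df_at_tmax, cmp$human_df_at_tmax)), con)
  write.csv(cmp$relative_thickness_table, con, row.names = FALSE)
  close(con)
  if (verbose) print(cmp)
  invisible(list(murine = rm_, human = rh, comparison = cmp, path = path))
}
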