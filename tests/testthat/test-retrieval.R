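synthetic_stack <- function(a0, v, phi, n_steps, dims = c(2L, 2L)) {
  frames <- array(0, c(dims, n_steps))
  for (k in seq_len(n_steps))
    frames[, , k] <- a0 * (1 + v * cos(2 * pi * (k - 1) / n_steps + phi))
  list(frames = frames, n_steps = n_steps,
       step_positions = (seq_len(n_steps) - 1) * 2e-6 / n_steps)
}

test_that("Fourier retrieval recovers a sinusoidal stepping curve exactly", {
  st <- synthetic_stack(100, 0.4, 0.7, 8L)
  r <- fourier_retrieve(st)
  expect_equal(r$a0, matrix(100, 2, 2))
  expect_equal(r$visibility, matrix(0.4, 2, 2))
  expect_equal(r$phi, matrix(0.7, 2, 2))
  # exact for any number of steps >= 3
  for (n in c(3L, 5L, 16L)) {
    rn <- fourier_retrieve(synthetic_stack(42, 0.25, -1.2, n))
    expect_equal(rn$a0[1, 1], 42, tolerance = 1e-12)
    expect_equal(rn$visibility[1, 1], 0.25, tolerance = 1e-12)
    expect_equal(rn$phi[1, 1], -1.2, tolerance = 1e-12)
  }
  # constant frames have zero visibility
  expect_equal(fourier_retrieve(synthetic_stack(7, 0, 0, 8L))$visibility,
               matrix(0, 2, 2))
})

test_that("GI images combine object and reference stacks per pixel", {
  ref <- synthetic_stack(100, 0.5, 0.2, 8L)
  obj <- synthetic_stack(80, 0.3, 0.9, 8L)
  gi <- compute_gi_images(obj, ref)
  expect_equal(gi$transmission, matrix(0.8, 2, 2))
  expect_equal(gi$dark_field, matrix(0.6, 2, 2))
  expect_equal(gi$differential_phase, matrix(0.7, 2, 2), tolerance = 1e-12)
  # identical stacks: df = 1, T = 1, dphi = 0
  same <- compute_gi_images(ref, ref)
  expect_equal(same$dark_field, matrix(1, 2, 2))
  expect_equal(same$transmission, matrix(1, 2, 2))
  expect_equal(same$differential_phase, matrix(0, 2, 2))
  # halving the object frames halves T, leaves df unchanged
  half <- obj
  half$frames <- obj$frames / 2
  gih <- compute_gi_images(half, ref)
  expect_equal(gih$transmission, matrix(0.4, 2, 2))
  expect_equal(gih$dark_field, gi$dark_field)
  # differential phase is wrapped into (-pi, pi]
  wrap <- synthetic_stack(80, 0.3, 3.0, 8L)
  giw <- compute_gi_images(wrap, synthetic_stack(100, 0.5, -3.0, 8L))
  expect_true(all(giw$differential_phase > -pi & giw$differential_phase <= pi))
  expect_equal(giw$differential_phase[1, 1], 6 - 2 * pi, tolerance = 1e-12)
  # a reference without carrier fringe cannot be analyzed
  flat <- synthetic_stack(100, 0, 0, 8L)
  expect_error(compute_gi_images(obj, flat), "visibility")
})

test_that("acquisition produces a sinusoid-dominated reference stack", {
  g <- gi_geometry(fov_pixels = c(2L, 2L), fine_sampling = 8L)
  ref <- acquire_stack(g, n_steps = 8L)
  expect_equal(dim(ref$frames), c(2L, 2L, 8L))
  expect_error(acquire_stack(g, n_steps = 2L), "at least 3")
  # stepping curve of one pixel: first harmonic dominates higher harmonics
  curve <- ref$frames[1, 1, ]
  sp <- Mod(fft(curve - mean(curve)))^2
  expect_gt(sp[2], 10 * max(sp[3:4]))
  r <- fourier_retrieve(ref)
  expect_gt(mean(r$visibility), 0.5)
  # the reference is deterministic: no randomness without noise
  ref2 <- acquire_stack(g, n_steps = 8L)
  expect_identical(ref$frames, ref2$frames)
})

test_that("a sphere-free slab produces unit dark field (absorption only)", {
  cfg <- mini_geometry("murine")
  g <- cfg$geometry
  ref <- acquire_stack(g)
  pack <- generate_sphere_pack(g, diameter = 60e-6, slab_thickness = 1.8e-3,
                               volume_fraction = 0, seed = 1L)
  expect_identical(nrow(pack$centers), 0L)
  obj <- acquire_stack(g, phantom = pack, materials = cfg$materials)
  gi <- compute_gi_images(obj, ref)
  # strong absorption, but no dark-field contrast
  expect_lt(mean(gi$transmission), 1)
  expect_lt(max(abs(gi$dark_field - 1)), 0.01)
  # zero-thickness phantom: the stack equals the reference stack
  pr0 <- structure(list(air_path = matrix(0, 1, 1), grid_spacing = g$grid_spacing,
                        slab_thickness = 0, overlap = "union"),
                   class = "projected_object")
  expect_equal(Mod(object_transmission(pr0, cfg$materials$muscle,
                                       cfg$materials$air, g$wavelength)), matrix(1, 1, 1))
})

test_that("dark field is invariant under uniform exposure rescaling", {
  cfg <- mini_geometry("murine")
  g <- cfg$geometry
  det1 <- detector_model(g$pixel_pitch, eak = 1e3)
  det2 <- detector_model(g$pixel_pitch, eak = 37)
  ref1 <- acquire_stack(g, detector = det1)
  ref2 <- acquire_stack(g, detector = det2)
  pack <- generate_sphere_pack(g, diameter = 60e-6, slab_thickness = 3.6e-3,
                               seed = 2L)
  obj1 <- acquire_stack(g, phantom = pack, detector = det1,
                        materials = cfg$materials)
  obj2 <- acquire_stack(g, phantom = pack, detector = det2,
                        materials = cfg$materials)
  gi1 <- compute_gi_images(obj1, ref1)
  gi2 <- compute_gi_images(obj2, ref2)
  expect_equal(gi2$dark_field, gi1$dark_field, tolerance = 1e-10)
  expect_equal(gi2$transmission, gi1$transmission, tolerance = 1e-10)
})

test_that("GI images export to TIFF and a self-describing CSV summary", {
  ref <- synthetic_stack(100, 0.5, 0.2, 8L)
  obj <- synthetic_stack(80, 0.3, 0.9, 8L)
  gi <- compute_gi_images(obj, ref)
  dir <- withr::local_tempdir()
  paths <- write_gi_images(gi, dir, prefix = "test")
  summ <- read.csv(file.path(dir, "test_summary.csv"))
  expect_equal(summ$image,
               c("transmission", "differential_phase", "dark_field"))
  expect_equal(summ$mean[3], 0.6, tolerance = 1e-12)
  expect_equal(summ$min[1], summ$max[1])  # uniform synthetic image
  if (requireNamespace("tiff", quietly = TRUE))
    expect_true(file.exists(file.path(dir, "test_dark_field.tif")))
})
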