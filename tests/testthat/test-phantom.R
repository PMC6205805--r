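test_that("nominal sphere count reproduces all six per-pixel counts", {
  px_m <- (100e-6)^2
  expect_identical(plan_sphere_count(px_m, 1.8e-3, 39e-6, 0.56), 325L)
  expect_identical(plan_sphere_count(px_m, 1.8e-3, 60e-6, 0.56), 89L)
  expect_identical(plan_sphere_count(px_m, 1.8e-3, 80e-6, 0.56), 38L)
  px_h <- (150e-6)^2
  expect_identical(plan_sphere_count(px_h, 25e-3, 200e-6, 0.56), 75L)
  expect_identical(plan_sphere_count(px_h, 25e-3, 300e-6, 0.56), 22L)
  expect_identical(plan_sphere_count(px_h, 25e-3, 400e-6, 0.56), 9L)
  expect_identical(plan_sphere_count(px_m, 1.8e-3, 60e-6, 0), 0L)
  expect_error(plan_sphere_count(-1, 1, 1, 0.5), "> 0")
  expect_error(plan_sphere_count(1, 1, 1, 1.2), "volume_fraction")
})

test_that("sphere packs are seeded, bounded and correctly counted", {
  p1 <- generate_sphere_pack(diameter = 60e-6, slab_thickness = 1.8e-3,
                             seed = 7L, lateral_extent = 100e-6)
  p2 <- generate_sphere_pack(diameter = 60e-6, slab_thickness = 1.8e-3,
                             seed = 7L, lateral_extent = 100e-6)
  expect_identical(p1$centers, p2$centers)
  # one 100 um pixel footprint at the nominal 0.56 fraction: 89 spheres
  expect_identical(nrow(p1$centers), 89L)
  expect_true(all(p1$centers[, 3] >= 0 & p1$centers[, 3] <= 1.8e-3))
  p3 <- generate_sphere_pack(diameter = 60e-6, slab_thickness = 1.8e-3,
                             seed = 8L, lateral_extent = 100e-6)
  expect_false(identical(p1$centers, p3$centers))
})

test_that("single-sphere projection gives the central chord", {
  pack <- generate_sphere_pack(diameter = 50e-6, slab_thickness = 200e-6,
                               seed = 1L, lateral_extent = 100e-6)
  pack$centers <- matrix(c(0, 0, 100e-6), 1, 3)
  pr <- project_air_path(pack, x = 0, y = 0)
  expect_equal(pr$air_path[1, 1], 50e-6)
  # ray missing the sphere sees no air
  pr2 <- project_air_path(pack, x = 30e-6, y = 0)
  expect_equal(pr2$air_path[1, 1], 0)
})

test_that("union projection is idempotent and order-independent", {
  pack <- generate_sphere_pack(diameter = 60e-6, slab_thickness = 0.5e-3,
                               seed = 3L, lateral_extent = 200e-6)
  x <- seq(-80e-6, 80e-6, by = 2e-6)
  pr <- project_air_path(pack, x = x, y = x)
  # duplicating every sphere changes nothing under union semantics
  dup <- pack
  dup$centers <- rbind(pack$centers, pack$centers)
  expect_equal(project_air_path(dup, x = x, y = x)$air_path, pr$air_path)
  # ... but doubles the sum-of-chords projection
  pr_sum <- project_air_path(pack, x = x, y = x, overlap = "sum")
  expect_equal(project_air_path(dup, x = x, y = x, overlap = "sum")$air_path,
               2 * pr_sum$air_path)
  # shuffling the sphere list changes nothing
  shuf <- pack
  shuf$centers <- pack$centers[sample.int(nrow(pack$centers)), , drop = FALSE]
  expect_equal(project_air_path(shuf, x = x, y = x)$air_path, pr$air_path)
  # union never exceeds sum, air path never exceeds slab thickness
  expect_true(all(pr$air_path <= pr_sum$air_path + 1e-15))
  expect_true(all(pr$air_path <= pack$slab_thickness + 1e-15))
})

test_that("union projection agrees with a voxel z-marching oracle", {
  pack <- generate_sphere_pack(diameter = 60e-6, slab_thickness = 0.4e-3,
                               volume_fraction = 0.15, seed = 11L,
                               lateral_extent = 350e-6)
  expect_gte(nrow(pack$centers), 50L)
  x <- seq(-60e-6, 60e-6, length.out = 25)
  y <- seq(-60e-6, 60e-6, length.out = 25)
  exact <- project_air_path(pack, x = x, y = y)$air_path
  step <- pack$diameter / 200
  vox <- voxel_air_path(pack, x, y, step)
  # each chord boundary is resolved to within half a voxel step; allow a
  # few boundaries per ray
  expect_lt(max(abs(exact - vox)), 4 * step)
})

test_that("realized union air fraction of a dense pack is below nominal", {
  geom <- gi_geometry(fov_pixels = c(1L, 1L), fine_sampling = 8L,
                      guard_periods = 4L)
  fr <- sapply(1:10, function(s) {
    pack <- generate_sphere_pack(geom, 60e-6, 1.8e-3, 0.56, seed = s)
    pr <- project_air_path(pack, geometry = geom)
    mean(pr$air_path) / pack$slab_thickness
  })
  # union of overlapping spheres at nominal 0.56: about 1 - exp(-0.56)
  expect_true(all(fr < 0.56))
  expect_equal(mean(fr), 1 - exp(-0.56), tolerance = 0.05)
  # realized fraction is stable across seeds
  expect_lt(sd(fr) / mean(fr), 0.05)
})

test_that("object transmission follows the projection approximation", {
  air <- material_optics(2.71e-10, 1.42e-13, "air")
  mus <- material_optics(3.10e-7, 1.78e-10, "muscle")
  wl <- wavelength_from_energy(27.7)
  # all-tissue ray at t = 1.8 mm: |O| = exp(-2*pi/lambda * beta * t)
  pr <- structure(list(air_path = matrix(0, 1, 1), grid_spacing = 1e-6,
                       slab_thickness = 1.8e-3, overlap = "union"),
                  class = "projected_object")
  o <- object_transmission(pr, mus, air, wl)
  expect_equal(Mod(o[1, 1]), exp(-2 * pi * 1.78e-10 * 1.8e-3 / wl),
               tolerance = 1e-12)
  expect_equal(Arg(o[1, 1]),
               ((2 * pi / wl * 3.10e-7 * 1.8e-3 + pi) %% (2 * pi)) - pi,
               tolerance = 1e-6)
  # t = 0: uniform unit transmission
  pr0 <- structure(list(air_path = matrix(0, 2, 2), grid_spacing = 1e-6,
                        slab_thickness = 0, overlap = "union"),
                   class = "projected_object")
  expect_equal(object_transmission(pr0, mus, air, wl),
               matrix(1 + 0i, 2, 2))
  # doubling a homogeneous slab squares the transmission
  pr2 <- pr
  pr2$slab_thickness <- 3.6e-3
  expect_equal(object_transmission(pr2, mus, air, wl)[1, 1],
               o[1, 1]^2, tolerance = 1e-10)
  # |O| <= 1 for nonnegative beta with air chords present
  pr3 <- structure(list(air_path = matrix(0.5e-3, 1, 1), grid_spacing = 1e-6,
                        slab_thickness = 1.8e-3, overlap = "union"),
                   class = "projected_object")
  expect_lte(Mod(object_transmission(pr3, mus, air, wl)[1, 1]), 1)
  # union projection with air path above t is inconsistent
  pr_bad <- pr3
  pr_bad$air_path <- matrix(2e-3, 1, 1)
  expect_error(object_transmission(pr_bad, mus, air, wl), "exceeds")
})

test_that("sphere packs round-trip through CSV", {
  pack <- generate_sphere_pack(diameter = 60e-6, slab_thickness = 1e-3,
                               seed = 5L, lateral_extent = 150e-6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_sphere_pack(pack, path)
  back <- read_sphere_pack(path)
  expect_equal(back$centers, pack$centers, ignore_attr = TRUE)
  expect_equal(back$diameter, pack$diameter)
  expect_equal(back$slab_thickness, pack$slab_thickness)
  expect_identical(back$seed, pack$seed)
})
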