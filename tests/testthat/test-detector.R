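test_that("pixel binning conserves intensity and averages fine structure", {
  g <- gi_geometry(fov_pixels = c(2L, 2L), fine_sampling = 8L,
                   guard_periods = 4L)
  gr <- darkfieldsim:::fine_grid(g)
  k <- gr$samples_per_pixel
  # uniform fine intensity c: every pixel reads c * k^2
  intens <- matrix(3.5, gr$nx, gr$ny)
  img <- bin_to_pixels(intens, g, grid = gr)
  expect_equal(dim(img$values), c(2L, 2L))
  expect_true(all(abs(img$values - 3.5 * k^2) < 1e-9))
  # conservation over the field of view
  intens2 <- matrix(runif(gr$nx * gr$ny), gr$nx, gr$ny)
  img2 <- bin_to_pixels(intens2, g, grid = gr)
  expect_equal(sum(img2$values),
               sum(intens2[gr$fov_ix, gr$fov_iy]), tolerance = 1e-12)
  # a fine checkerboard averages to equal pixels
  cb <- matrix(rep_len(c(0, 1), gr$nx * gr$ny), gr$nx, gr$ny)
  img3 <- bin_to_pixels(cb, g, grid = gr)
  expect_lt(diff(range(img3$values)) / mean(img3$values), 1e-10)
})

test_that("exposure scaling is linear in EAK", {
  img <- structure(list(values = matrix(2, 3, 3), step_position = 0),
                   class = "pixel_image")
  expect_true(all(scale_exposure(img, eak = 0)$values == 0))
  s1 <- scale_exposure(img, eak = 100, calibration = 2, reference_mean = 4)
  s2 <- scale_exposure(img, eak = 200, calibration = 2, reference_mean = 4)
  expect_equal(s2$values, 2 * s1$values)
  expect_equal(s1$values[1, 1], 2 * 2 * 100 / 4)
  expect_error(scale_exposure(img, eak = -1), ">= 0")
})

test_that("system blur preserves the mean and follows the closed-form response", {
  n <- 64L
  pitch <- 100e-6
  det_id <- detector_model(pitch)
  img <- structure(list(values = matrix(rnorm(n * n, 10), n, n),
                        step_position = 0), class = "pixel_image")
  # ideal MTF and zero focal spot: identity
  expect_identical(apply_system_blur(img, det_id)$values, img$values)
  # uniform image unchanged by any valid blur
  f_nyq <- 1 / (2 * pitch)
  mtf <- data.frame(freq = c(0, 2 * f_nyq), value = c(1, 0.2))
  det <- detector_model(pitch, mtf_curve = mtf, focal_spot_sigma = 50e-6)
  u <- img; u$values <- matrix(4, n, n)
  expect_equal(apply_system_blur(u, det)$values, u$values, tolerance = 1e-12)
  # sinusoid at a DFT frequency: amplitude times mtf(f) * gaussian(f)
  kcyc <- 8L
  f <- kcyc / (n * pitch)
  x <- (0:(n - 1)) * pitch
  s <- img; s$values <- matrix(10 + 2 * cos(2 * pi * f * x), n, n)
  out <- apply_system_blur(s, det)$values
  amp_out <- 2 * Mod(mean(out[, 1] * exp(-2i * pi * (0:(n - 1)) * kcyc / n)))
  expected <- 2 * approx(mtf$freq, mtf$value, f)$y *
    exp(-2 * pi^2 * (50e-6)^2 * f^2)
  expect_equal(amp_out, expected, tolerance = 1e-8)
  # an MTF that is not 1 at zero frequency is rejected
  expect_error(detector_model(pitch, mtf_curve = data.frame(freq = c(0, 1),
                                                            value = c(0.9, 0.2))),
               "zero frequency")
})

test_that("noise is seeded, optional, and Poisson-scaled", {
  det_off <- detector_model(100e-6, noise = FALSE)
  img <- structure(list(values = matrix(100, 100, 100), step_position = 0),
                   class = "pixel_image")
  expect_identical(add_noise(img, det_off, seed = 1L)$values, img$values)
  det_on <- detector_model(100e-6, noise = TRUE)
  n1 <- add_noise(img, det_on, seed = 5L)
  n2 <- add_noise(img, det_on, seed = 5L)
  expect_identical(n1$values, n2$values)
  expect_false(identical(n1$values, add_noise(img, det_on, seed = 6L)$values))
  # flat NPS, constant image c: empirical variance approx c (Poisson scaling)
  expect_equal(var(as.vector(n1$values - img$values)), 100, tolerance = 0.05)
  # mean of many noisy realizations converges to the noiseless image
  small <- structure(list(values = matrix(50, 10, 10), step_position = 0),
                     class = "pixel_image")
  acc <- matrix(0, 10, 10)
  for (s in 1:1000) acc <- acc + add_noise(small, det_on, seed = s)$values
  expect_lt(mean(abs(acc / 1000 - 50) / 50), 0.01)
  img_neg <- img; img_neg$values[1, 1] <- -1
  expect_error(add_noise(img_neg, det_on, seed = 1L), "nonnegative")
})

test_that("measured frequency curves are validated on ingestion", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# freq[cyc/mm] value", "0 1", "5 0.2"), path)
  cv <- read_frequency_curve(path, normalize_zero = TRUE)
  expect_equal(cv$value, c(1, 0.2))
  expect_equal(cv$freq, c(0, 5000))  # cycles/m
  # linear interpolation between tabulated points
  expect_equal(darkfieldsim:::curve_value(cv, 2500), 0.6)
  # empty file is a format error
  empty <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), empty)
  expect_error(read_frequency_curve(empty))
  # non-monotone frequency axis is rejected
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 1", "2 0.5", "1 0.2"), bad)
  expect_error(read_frequency_curve(bad), "increasing")
})
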