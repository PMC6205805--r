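# Independent brute-force oracles used to validate the analytic projection
# and the optics chain on tiny problems.

# Voxel z-marching projection oracle: for each ray, march z in steps of
# `step` and count midpoints inside any sphere (direct sphere-membership
# test, no chord arithmetic). Returns the union air path per ray.
voxel_air_path <- function(pack, x, y, step) {
  t <- pack$slab_thickness
  z <- seq(step / 2, t - step / 2, by = step)
  cen <- pack$centers
  r2 <- (pack$diameter / 2)^2
  out <- matrix(0, length(x), length(y))
  for (j in seq_along(y)) {
    for (i in seq_along(x)) {
      d2 <- (cen[, 1] - x[i])^2 + (cen[, 2] - y[j])^2
      near <- which(d2 < r2)
      if (!length(near)) next
      inside <- rep(FALSE, length(z))
      for (s in near)
        inside <- inside | ((z - cen[s, 3])^2 < r2 - d2[s])
      out[i, j] <- sum(inside) * step
    }
  }
  out
}

# small geometry used by fast chain tests: 2x2 pixels, reduced sampling
mini_geometry <- function(preset = "murine", fine_sampling = 8L, ...) {
  cfg <- load_preset(preset, fov_pixels = c(2L, 2L),
                     fine_sampling = fine_sampling, ...)
  cfg
}
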