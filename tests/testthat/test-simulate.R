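test_that("generators are reproducible under a fixed seed", {
  a <- sim_filaments(c(4, 64, 64), 8, seed = 40)
  b <- sim_filaments(c(4, 64, 64), 8, seed = 40)
  expect_identical(a, b)
  expect_equal(sim_filaments(c(1, 64, 64), 0), array(0, c(1, 64, 64)))
  n1 <- add_noise(a, 50, "gaussian", seed = 41)
  n2 <- add_noise(a, 50, "gaussian", seed = 41)
  expect_identical(n1, n2)
  b1 <- sim_beads(c(8, 64, 64), 5, seed = 42)
  b2 <- sim_beads(c(8, 64, 64), 5, seed = 42)
  expect_identical(b1$centers, b2$centers)
})

test_that("filament images have a dark background mode and bright tail", {
  v <- sim_filaments(c(1, 128, 128), 20, seed = 43)
  expect_equal(max(v), 5000)
  expect_gt(mean(v < 0.05 * 5000), 0.5)   # mostly background
  expect_gt(mean(v > 0.5 * 5000), 0.005)  # but a real bright tail
})

test_that("the noise model has the stated standard deviation and decreasing SNR", {
  flat <- array(0, c(1, 128, 128))
  g <- add_noise(flat, 1e9, "gaussian", sigma = 10, seed = 44)
  expect_equal(sd(g), 10, tolerance = 0.05 * 10)
  expect_lt(abs(mean(g)), 3 * 10 / sqrt(length(g)))
  p <- add_noise(flat, 1e9, "poisson", sigma = 10, seed = 45)
  expect_equal(sd(p), 10, tolerance = 0.05 * 10)
  v <- sim_filaments(c(1, 128, 128), 20, seed = 46)
  snrs <- sapply(c(20, 60, 180), function(div)
    estimate_snr(add_noise(v, div, "gaussian", seed = 47)[1, , ]))
  expect_true(all(diff(snrs) < 0))
})

test_that("induced affine shifts are recovered by the estimator", {
  p <- affine_params(t_x = 1.2, t_y = -0.8, m_x = 1.002, r_z = 0.3)
  pair <- sim_registration_pair(c(1, 160, 160), p, n_filaments = 25,
                                seed = 48)
  fit <- quiet_global(pair$ref, pair$sub)
  expect_equal(as.numeric(fit$params)[c(1, 2, 4, 5, 7)],
               as.numeric(p)[c(1, 2, 4, 5, 7)], tolerance = 0.05)
  v <- sim_filaments(c(1, 64, 64), 8, seed = 49)
  expect_equal(induce_affine(v, affine_params()), v, tolerance = 1e-12)
})

test_that("small induced shifts compose approximately additively", {
  v <- sim_filaments(c(1, 128, 128), 20, seed = 50)[1, , ]
  p1 <- affine_params(t_x = 0.4)
  p2 <- affine_params(t_y = -0.3)
  both <- induce_affine(induce_affine(v, p1), p2)
  onep <- induce_affine(v, affine_params(t_x = 0.4, t_y = -0.3))
  expect_lt(sqrt(mean((both[9:120, 9:120] - onep[9:120, 9:120])^2)),
            0.01 * diff(range(v)))
})

test_that("induced local fields behave as pull-map displacements", {
  v <- sim_filaments(c(1, 128, 128), 20, seed = 51)[1, , ]
  z <- induce_local_field(v, amplitude = 0)
  expect_equal(z$volume, v, tolerance = 1e-9)
  expect_equal(max(abs(c(z$field$x, z$field$y))), 0)
  # a constant field is a uniform shift of the content
  ind <- induce_local_field(v, amplitude = 1, n_modes = 1, seed = 52)
  # manually constant field: content moved by +S
  gx <- matrix(0:127, 128, 128, byrow = TRUE)
  gy <- matrix(0:127, 128, 128)
  warped <- remap_image(v, list(map_y = gy, map_x = gx - 1))
  pk <- locate_peak_subpixel(phase_correlate(v, warped))
  expect_equal(pk$shift, c(0, 1), tolerance = 0.05)
  # sinusoidal field equals per-pixel interpolation through remap_image
  ind2 <- induce_local_field(v, amplitude = 0.8, seed = 53)
  oracle <- remap_image(v, list(map_y = gy - ind2$field$y,
                                map_x = gx - ind2$field$x))
  expect_equal(ind2$volume, oracle, tolerance = 1e-12)
  expect_error(induce_local_field(v, amplitude = 5), "amplitude")
})

test_that("bead volumes honor the two-layer geometry and channel offsets", {
  b <- sim_beads(c(16, 96, 96), 12,
                 channel_offsets = list(c(0, 0, 0), c(0, 0, 0)), seed = 54)
  expect_identical(b$channels[[1]], b$channels[[2]])
  zs <- b$centers$z
  expect_true(all(b$centers$layer %in% 1:2))
  expect_true(all(abs(zs[b$centers$layer == 1] - 0.3 * 15) <= 0.5 + 1e-9))
  expect_true(all(abs(zs[b$centers$layer == 2] - 0.7 * 15) <= 0.5 + 1e-9))
  # a single bead's center is recovered by the Gaussian fit
  one <- sim_beads(c(16, 64, 64), 1, seed = 55)
  tb <- fit_beads_3d(one$channels[[1]])
  expect_equal(nrow(tb), 1)
  expect_equal(c(tb$z, tb$y, tb$x),
               c(one$centers$z, one$centers$y, one$centers$x),
               tolerance = 0.05)
})
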