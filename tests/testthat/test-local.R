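test_that("variance threshold and tile variance follow their formulas", {
  set.seed(20)
  a <- matrix(rnorm(64 * 64, sd = 10), 64, 64)
  b <- matrix(rnorm(64 * 64, sd = 10), 64, 64)
  expect_equal(variance_threshold(a, b, c = 0.1),
               0.1 * var(as.vector(a)) * var(as.vector(b)))
  expect_equal(variance_threshold(matrix(5, 16, 16), matrix(2, 16, 16)), 0)
  # tile variance is the mean of the two central-quarter variances
  expect_equal(tile_variance(a, b),
               (var(as.vector(a[17:48, 17:48])) +
                  var(as.vector(b[17:48, 17:48]))) / 2)
  expect_equal(tile_variance(matrix(1, 16, 16), matrix(1, 16, 16)), 0)
  # signal confined outside the central quarter is gated out
  edge <- matrix(0, 16, 16); edge[1, ] <- 100
  expect_equal(tile_variance(edge, edge), 0)
})

test_that("tile shifts are measured on the interleaved grid with gating", {
  img <- project_max(sim_filaments(c(1, 256, 256), 60, seed = 21), "z")
  g0 <- measure_tile_shifts(img, img, n_tiles = 4)
  expect_equal(dim(g0$tx), c(8L, 8L))
  expect_true(any(g0$valid))
  expect_lt(max(abs(c(g0$tx[g0$valid], g0$ty[g0$valid]))), 0.01)
  # uniform translation
  sub <- fourier_shift(img, 0, 1)
  g1 <- measure_tile_shifts(img, sub, n_tiles = 4)
  expect_equal(mean(g1$tx[g1$valid]), 1, tolerance = 0.1)
  expect_equal(mean(abs(g1$ty[g1$valid])), 0, tolerance = 0.1)
  # an empty quadrant is invalid
  img2 <- img
  img2[1:128, 1:128] <- 0
  g2 <- measure_tile_shifts(img2, img2, n_tiles = 4)
  expect_false(any(g2$valid[2:3, 2:3]))
  expect_error(measure_tile_shifts(matrix(0, 64, 64), matrix(0, 64, 64)),
               "contrast")
})

test_that("gap filling grows a mean-filter window and is idempotent", {
  mk <- function(tx, valid) {
    structure(list(tx = tx, ty = tx, valid = valid,
                   truncated = matrix(FALSE, nrow(tx), ncol(tx)),
                   window = c(16, 16), stride = c(8, 8), n_tiles = 4),
              class = "local_shift_map")
  }
  # one hole surrounded by a constant
  tx <- matrix(2, 8, 8); valid <- matrix(TRUE, 8, 8)
  tx[4, 4] <- NA; valid[4, 4] <- FALSE
  f <- fill_empty(mk(tx, valid))
  expect_equal(f$tx[4, 4], 2)
  expect_true(all(f$valid))
  expect_false(f$measured[4, 4])
  # one valid tile propagates everywhere
  tx2 <- matrix(NA_real_, 8, 8); v2 <- matrix(FALSE, 8, 8)
  tx2[2, 7] <- -1.5; v2[2, 7] <- TRUE
  f2 <- fill_empty(mk(tx2, v2))
  expect_true(all(f2$valid))
  expect_equal(unique(as.vector(f2$tx)), -1.5)
  # checkerboard equals the explicit snapshot-mean oracle (3x3 window)
  set.seed(22)
  tx3 <- matrix(rnorm(64), 8, 8)
  v3 <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0)
  tx3[!v3] <- NA
  f3 <- fill_empty(mk(tx3, v3))
  oracle <- tx3
  for (i in 1:8) for (j in 1:8) if (!v3[i, j]) {
    ri <- max(1, i - 1):min(8, i + 1)
    ci <- max(1, j - 1):min(8, j + 1)
    oracle[i, j] <- mean(tx3[ri, ci][v3[ri, ci]])
  }
  expect_equal(f3$tx, oracle)
  # filling twice changes nothing
  f3b <- fill_empty(f3)
  expect_equal(f3b$tx, f3$tx)
  expect_error(fill_empty(mk(matrix(NA_real_, 8, 8), matrix(FALSE, 8, 8))),
               "no valid")
})

test_that("Fourier upsampling preserves constants and pure modes", {
  g <- structure(list(tx = matrix(1.5, 8, 8), ty = matrix(-0.5, 8, 8),
                      valid = matrix(TRUE, 8, 8),
                      truncated = matrix(FALSE, 8, 8),
                      window = c(32, 32), stride = c(16, 16), n_tiles = 4),
                 class = "local_shift_map")
  up <- upsample_map(g, c(128, 128))
  expect_equal(range(up$x), c(1.5, 1.5), tolerance = 1e-9)
  expect_equal(range(up$y), c(-0.5, -0.5), tolerance = 1e-9)
  # a single cosine mode survives at full resolution (phase-aligned to the
  # tile centers)
  centers <- (0:7) * 16 + 16 - 0.5
  gx <- matrix(cos(2 * pi * centers / 128), 8, 8, byrow = TRUE)
  g2 <- g; g2$tx <- gx
  up2 <- upsample_map(g2, c(128, 128))
  xs <- 0:127
  expect_equal(up2$x[1, ], cos(2 * pi * xs / 128), tolerance = 1e-6)
})

test_that("local refinement is inert on identical images and recovers fields", {
  img <- project_max(sim_filaments(c(1, 256, 256), 60, seed = 23), "z")
  fit0 <- refine_local(img, img, min_window = 60)
  expect_lt(max(abs(c(fit0$displacement$x, fit0$displacement$y))), 0.05)
  # smooth induced field (amplitude 1 px), noise-free
  ind <- induce_local_field(img, amplitude = 1, seed = 24)
  fit <- suppressWarnings(refine_local(img, ind$volume, min_window = 60))
  err <- mean_local_error(fit$displacement, ind$field, fit$mask)
  expect_lt(err, 0.1)
})

test_that("lowering the gate constant never invalidates a valid tile", {
  img <- project_max(sim_filaments(c(1, 256, 256), 20, seed = 25), "z")
  sub <- fourier_shift(img, 0.5, -0.5)
  g_hi <- measure_tile_shifts(img, sub, n_tiles = 4, c = 0.1)
  g_lo <- measure_tile_shifts(img, sub, n_tiles = 4, c = 0.01)
  expect_true(all(g_lo$valid[g_hi$valid]))
})

test_that("local error declines with SNR on average", {
  errs <- sapply(c(20, 200), function(div) {
    img <- sim_filaments(c(8, 256, 256), 120, seed = 26)
    ind <- induce_local_field(img, amplitude = 1, seed = 27)
    ref <- project_max(add_noise(img, div, "gaussian", seed = 28), "z")
    sub <- project_max(add_noise(ind$volume, div, "gaussian", seed = 29), "z")
    fit <- suppressWarnings(refine_local(ref, sub, min_window = 60))
    mean_local_error(fit$displacement, ind$field, fit$mask)
  })
  expect_lt(errs[1], errs[2])
})
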