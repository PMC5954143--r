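test_that("contrast-section selection follows per-section variance", {
  vol <- array(0, c(30, 16, 16))
  set.seed(11)
  for (z in 10:20) vol[z, , ] <- matrix(rnorm(256, sd = z), 16, 16)
  sec <- select_contrast_sections(vol)
  expect_true(all(sec >= 10 & sec <= 20))
  expect_true(20 %in% sec)  # the max-variance section
  # uniform variance -> full range
  vol2 <- array(rnorm(30 * 256), c(30, 16, 16))
  expect_true(length(select_contrast_sections(vol2, frac = 0.01)) > 25)
  expect_error(select_contrast_sections(array(1, c(5, 8, 8))), "no contrast")
  # two slabs: range contains the globally strongest
  vol3 <- array(0, c(30, 16, 16))
  vol3[5:8, , ] <- array(rnorm(4 * 256, sd = 2), c(4, 16, 16))
  vol3[20:23, , ] <- array(rnorm(4 * 256, sd = 5), c(4, 16, 16))
  v <- vapply(1:30, function(z) var(as.vector(vol3[z, , ])), 0)
  expect_true(which.max(v) %in% select_contrast_sections(vol3))
})

test_that("maximum projection equals the brute-force loop", {
  set.seed(12)
  vol <- array(rnorm(10 * 12 * 14), c(10, 12, 14))
  pz <- project_max(vol, "z")
  oracle <- matrix(0, 12, 14)
  for (y in 1:12) for (x in 1:14) oracle[y, x] <- max(vol[, y, x])
  expect_equal(pz, oracle)
  px <- project_max(vol, "x", sections = 3:10)
  oracle2 <- matrix(0, 10, 12)
  for (z in 1:10) for (y in 1:12) oracle2[z, y] <- max(vol[z, y, 3:10])
  expect_equal(px, oracle2)
  expect_equal(project_max(vol[1, , , drop = FALSE], "z"),
               matrix(vol[1, , ], 12, 14))
})

test_that("quadrant vectors reflect pure translation and rotation patterns", {
  # broadband texture: phase correlation needs energy across the masked
  # band, not just at the lowest frequencies
  img <- smooth_image(128, seed = 13, sigma_f = 0.12) * 100
  qv0 <- measure_quadrant_vectors(img, img)
  for (nm in c("a", "b", "c", "d"))
    expect_equal(qv0[[nm]], c(0, 0), tolerance = 1e-6)
  # global circular translation moves every quadrant equally (up to the
  # content that crosses quadrant boundaries)
  sub <- fourier_shift(img, -1, 2)
  qv <- measure_quadrant_vectors(img, sub)
  for (nm in c("a", "b", "c", "d"))
    expect_equal(qv[[nm]], c(2, -1), tolerance = 0.35)
  # rotation: tangential field, diagonal pairs roughly antiparallel
  rot <- induce_affine(img, affine_params(r_z = 1))
  qvr <- suppressWarnings(measure_quadrant_vectors(img, rot))
  expect_equal(qvr$a + qvr$c, c(0, 0), tolerance = 0.5)
  expect_equal(qvr$b + qvr$d, c(0, 0), tolerance = 0.5)
  expect_lt(sum(qvr$a * qvr$c), 0)     # antiparallel
  expect_error(measure_quadrant_vectors(img, matrix(0, 128, 128)),
               "all-zero|quadrant")
})

test_that("quadrant decomposition inverts synthetic forward fields", {
  # pure uniform vectors: translation only
  qv <- structure(list(a = c(1, 0), b = c(1, 0), c = c(1, 0), d = c(1, 0),
                       centers = NULL), class = "quadrant_vectors")
  dec <- decompose_quadrants(qv, c(256, 256))
  expect_equal(dec$t, c(1, 0))
  expect_equal(dec$r_z, 0)
  expect_equal(dec$m, c(1, 1))
  # pure rotation: the pull-map field d(p) = (th p_y, -th p_x)
  th <- 0.5 * pi / 180
  q <- 64
  mkv <- function(p) c(th * p[2], -th * p[1])
  qvr <- structure(list(a = mkv(c(q, q)), b = mkv(c(-q, q)),
                        c = mkv(c(-q, -q)), d = mkv(c(q, -q))),
                   class = "quadrant_vectors")
  decr <- decompose_quadrants(qvr, c(256, 256))
  expect_equal(decr$t, c(0, 0), tolerance = 1e-9)
  expect_equal(decr$r_z, 0.5, tolerance = 0.01)
  expect_equal(decr$m, c(1, 1), tolerance = 1e-6)
  # pure per-axis magnification of the content by 0.998:
  # pull-field alpha = 1/m - 1
  al <- 1 / 0.998 - 1
  mkm <- function(p) c(al * p[1], 0)
  qvm <- structure(list(a = mkm(c(q, q)), b = mkm(c(-q, q)),
                        c = mkm(c(-q, -q)), d = mkm(c(q, -q))),
                   class = "quadrant_vectors")
  decm <- decompose_quadrants(qvm, c(256, 256))
  expect_equal(decm$r_z, 0, tolerance = 1e-9)
  expect_equal(decm$m[1], 0.998, tolerance = 5e-4)
  expect_equal(decm$m[2], 1, tolerance = 1e-9)
})

test_that("global estimation recovers induced parameters and stays consistent", {
  p_true <- affine_params(t_x = 1.5, t_y = -2, m_x = 0.997, m_y = 1.002,
                          r_z = -0.4)
  pair <- sim_registration_pair(c(1, 192, 192), p_true, n_filaments = 25,
                                seed = 14)
  fit <- quiet_global(pair$ref, pair$sub)
  err <- as.numeric(fit$params) - as.numeric(p_true)
  expect_lt(max(abs(err[1:2])), 0.1)
  expect_lt(max(abs(err[4:5])), 0.001)
  expect_lt(abs(err[7]), 0.05)
  # forward and backward fits are mutually inverse
  bwd <- quiet_global(array(pair$sub, c(1, 192, 192)),
                      array(pair$ref, c(1, 192, 192)))
  comp <- affine_compose(fit$params, bwd$params)
  expect_equal(as.numeric(comp)[c(1, 2, 7)], c(0, 0, 0), tolerance = 0.1)
  expect_equal(as.numeric(comp)[4:5], c(1, 1), tolerance = 0.001)
})

test_that("identical channels give the identity in one iteration", {
  vol <- sim_filaments(c(8, 96, 96), 12, seed = 15)
  fit <- quiet_global(vol, vol)
  expect_equal(as.numeric(fit$params), as.numeric(affine_params()),
               tolerance = 1e-3)
  expect_true(fit$converged)
  expect_equal(nrow(fit$iterations), 1)
})

test_that("a pure z shift on a thin stack uses the z fallback", {
  vol <- sim_filaments(c(12, 96, 96), 12, seed = 16)
  sub <- apply_affine(vol, affine_params(t_z = -1.5))  # content moved +1.5
  fit <- quiet_global(vol, sub)
  expect_true(fit$z_fallback)
  expect_equal(fit$params$t_z, 1.5, tolerance = 0.1)
  expect_equal(c(fit$params$t_x, fit$params$t_y), c(0, 0), tolerance = 0.1)
  expect_equal(c(fit$params$m_x, fit$params$m_y), c(1, 1), tolerance = 5e-3)
})

test_that("noise robustness: mean lateral error under 30 nm at SNR above 2", {
  p_true <- affine_params(t_x = -2, t_y = -3, m_x = 0.998, m_y = 0.999,
                          r_z = 0.5)
  errs <- c()
  for (s in 1:4) {
    pair <- sim_registration_pair(c(16, 256, 256), p_true, n_filaments = 30,
                                  seed = 300 + s, divisor = 150,
                                  noise_kind = "gaussian")
    ref <- project_max(pair$ref, "z")
    sub <- project_max(pair$sub, "z")
    expect_gte(estimate_snr(ref), 2)
    fit <- quiet_global(ref, sub)
    e <- as.numeric(fit$params) - as.numeric(p_true)
    d <- params_to_deviation(affine_params(t_x = e[1], t_y = e[2],
                                           m_x = 1 + e[4], m_y = 1 + e[5],
                                           r_z = e[7]),
                             c(256, 256), 78)
    errs <- c(errs, d$total_2d)
  }
  expect_lt(mean(errs), 30)
})
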