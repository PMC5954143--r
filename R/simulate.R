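# Synthetic fixtures with the statistical structure of the validation
# simulations: filament-like stacks, bead volumes, induced affine and local
# shifts, and the divide-plus-noise model.

# Separable Gaussian blur of a (nz, ny, nx) array (or matrix) via FFT;
# sigma in pixels per axis, 0 disables that axis.
gaussian_blur <- function(vol, sigma) {
  d <- dim(vol)
  ker <- lapply(seq_along(d), function(a) {
    if (sigma[a] <= 0 || d[a] == 1) return(rep(1, d[a]))
    f <- fft_freq(d[a])
    exp(-2 * pi^2 * sigma[a]^2 * f^2)
  })
  g <- if (length(d) == 2) outer(ker[[1]], ker[[2]])
  else outer(outer(ker[[1]], ker[[2]]), ker[[3]])
  dim(g) <- d
  Re(stats::fft(stats::fft(vol) * g, inverse = TRUE)) / length(vol)
}

#' Generate a filament-like image stack
#'
#' Renders smooth curvilinear filaments (random walks with slowly turning
#' direction, emulating tubulin/actin staining) convolved with a Gaussian
#' point-spread function (sigma 2 px lateral, 1 section axial), and
#' normalizes the stack to a maximum of 5000 counts so that noise divisors
#' in the 20-500 range produce average SNRs spanning roughly 1.5-20.
#'
#' @param shape `c(nz, ny, nx)` (use `nz = 1` for a 2D image); lateral axes
#'   must be at least 64 px.
#' @param n_filaments Number of filaments (default 15).
#' @param seed Optional RNG seed for reproducibility.
#' @param psf_sigma `c(z, y, x)` Gaussian PSF sigma in pixels/sections.
#' @return A `(nz, ny, nx)` array with background 0 and maximum 5000.
#' @export
sim_filaments <- function(shape, n_filaments = 15, seed = NULL,
                          psf_sigma = c(1, 2, 2)) {
  if (!is.null(seed)) set.seed(seed)
  if (length(shape) == 2) shape <- c(1L, shape)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  if (ny < 64 || nx < 64) stop("lateral axes must be at least 64 px")
  vol <- array(0, shape)
  if (n_filaments == 0) return(vol)
  for (f in seq_len(n_filaments)) {
    len <- round(stats::runif(1, 0.5, 1.5) * max(ny, nx))
    y <- stats::runif(1, 0.1 * ny, 0.9 * ny)
    x <- stats::runif(1, 0.1 * nx, 0.9 * nx)
    z <- stats::runif(1, 0.2 * max(nz - 1, 1), 0.8 * max(nz - 1, 1))
    ang <- stats::runif(1, 0, 2 * pi)
    zdrift <- stats::rnorm(1, 0, 0.02)
    amp <- stats::runif(1, 0.6, 1)
    for (s in seq_len(len)) {
      ang <- ang + stats::rnorm(1, 0, 0.06)
      y <- y + sin(ang); x <- x + cos(ang)
      z <- z + zdrift + stats::rnorm(1, 0, 0.01)
      iy <- round(y) + 1L; ix <- round(x) + 1L; iz <- round(z) + 1L
      if (iy >= 1 && iy <= ny && ix >= 1 && ix <= nx &&
          iz >= 1 && iz <= nz)
        vol[iz, iy, ix] <- vol[iz, iy, ix] + amp
    }
  }
  vol <- gaussian_blur(vol, psf_sigma)
  vol[vol < 0] <- 0
  # scale the filament cores (not the rare crossing hot-spots) to the
  # 5000-count ceiling, then clip: keeps the above-threshold mean high so
  # noise divisors of 20-500 span the intended SNR range
  ref_level <- stats::quantile(vol[vol > 0.05 * max(vol)], 0.9)
  if (ref_level > 0) vol <- vol * (5000 / ref_level)
  vol[vol > 5000] <- 5000
  vol
}

#' Induce a known global shift
#'
#' Forward-warps a volume so that [estimate_global()] applied to
#' (`vol`, result) recovers exactly the given parameters; margins falling
#' outside the image are zeroed.
#'
#' @param vol A `(nz, ny, nx)` array or matrix.
#' @param p The `affine_params7` to induce.
#' @return The warped volume.
#' @export
induce_affine <- function(vol, p) {
  apply_affine(vol, affine_invert(p))
}

#' Induce a smooth local shift field
#'
#' Builds a smooth 2D vector field as a sum of low-order sinusoids with a
#' given peak amplitude, applies it to every z-plane (pull map `I - S`, so
#' that the recovered local map equals `+S`), and returns both the warped
#' volume and the induced field for error scoring.
#'
#' @param vol A `(nz, ny, nx)` array or matrix.
#' @param amplitude Peak shift magnitude in pixels (must be <= 3; local
#'   distortions beyond that are outside the elastic model's regime).
#' @param n_modes Number of sinusoidal modes per component (default 3).
#' @param max_freq Highest spatial frequency of the modes in cycles per
#'   image extent (default 1: the field varies on the scale of the whole
#'   field of view, as slowly varying optical distortions do).
#' @param seed Optional RNG seed.
#' @return A list with `volume` (warped) and `field` (list of matrices `x`,
#'   `y` in pixels).
#' @export
induce_local_field <- function(vol, amplitude = 1, n_modes = 3,
                               max_freq = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (amplitude > 3) stop("amplitude must be <= 3 px")
  is2d <- is.matrix(vol)
  if (is2d) dim(vol) <- c(1L, dim(vol))
  d <- dim(vol)
  ny <- d[2]; nx <- d[3]
  gx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  gy <- matrix(seq_len(ny) - 1, ny, nx)
  field <- lapply(c("x", "y"), function(comp) {
    fld <- matrix(0, ny, nx)
    for (k in seq_len(n_modes)) {
      fy <- sample(0:max_freq, 1); fx <- sample(0:max_freq, 1)
      if (fy == 0 && fx == 0) fx <- 1
      ph <- stats::runif(1, 0, 2 * pi)
      fld <- fld + stats::runif(1, 0.5, 1) *
        sin(2 * pi * (fy * gy / ny + fx * gx / nx) + ph)
    }
    fld
  })
  names(field) <- c("x", "y")
  mx <- max(sqrt(field$x^2 + field$y^2))
  if (mx > 0) {
    field$x <- field$x * amplitude / mx
    field$y <- field$y * amplitude / mx
  }
  map <- list(map_y = gy - field$y, map_x = gx - field$x)
  out <- vol
  for (z in seq_len(d[1]))
    out[z, , ] <- remap_image(matrix(vol[z, , ], ny, nx), map)
  if (is2d) dim(out) <- d[2:3]
  list(volume = out, field = field)
}

#' Divide-plus-noise degradation
#'
#' Emulates low-light acquisition: the volume is divided by a constant and
#' noise of standard deviation `sigma` is added (Gaussian, or centered
#' Poisson with rate `sigma^2` so its standard deviation is exactly
#' `sigma`).
#'
#' @param vol Numeric array or matrix.
#' @param divisor Positive attenuation constant (the simulations use
#'   20-500).
#' @param noise_kind `"gaussian"` or `"poisson"`.
#' @param sigma Noise standard deviation (default 10).
#' @param seed Optional RNG seed.
#' @return The degraded volume.
#' @export
add_noise <- function(vol, divisor, noise_kind = c("gaussian", "poisson"),
                      sigma = 10, seed = NULL) {
  noise_kind <- match.arg(noise_kind)
  if (divisor <= 0) stop("divisor must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- length(vol)
  noise <- if (noise_kind == "gaussian") stats::rnorm(n, 0, sigma)
  else stats::rpois(n, sigma^2) - sigma^2
  vol / divisor + array(noise, dim(vol) %||% n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a two-layer bead volume
#'
#' Places Gaussian spots of known subpixel centers on two z-layers and
#' renders one volume per channel, each offset by a specified chromatic
#' shift.  Overlapping beads are allowed (downstream proximity filtering
#' must remove them).
#'
#' @param shape `c(nz, ny, nx)`.
#' @param n_beads Number of beads.
#' @param channel_offsets List of per-channel `c(dz, dy, dx)` offsets in
#'   pixels (the first is usually `c(0, 0, 0)` for the reference channel).
#' @param seed Optional RNG seed.
#' @param sigma `c(z, y, x)` Gaussian spot sigma in pixels.
#' @param intensity Peak intensity per bead.
#' @return A list with `channels` (list of `(nz, ny, nx)` arrays) and
#'   `centers` (data frame: bead, layer, z, y, x in 0-based pixels, for the
#'   reference geometry).
#' @export
sim_beads <- function(shape, n_beads, channel_offsets = list(c(0, 0, 0)),
                      seed = NULL, sigma = c(1.2, 1.8, 1.8),
                      intensity = 4000) {
  if (!is.null(seed)) set.seed(seed)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  layers <- c(0.3, 0.7) * (nz - 1)
  layer <- sample(1:2, n_beads, replace = TRUE)
  centers <- data.frame(
    bead = seq_len(n_beads),
    layer = layer,
    z = layers[layer] + stats::runif(n_beads, -0.5, 0.5),
    y = stats::runif(n_beads, 4, ny - 5),
    x = stats::runif(n_beads, 4, nx - 5))
  render <- function(off) {
    vol <- array(0, shape)
    for (b in seq_len(n_beads)) {
      cz <- centers$z[b] + off[1]
      cy <- centers$y[b] + off[2]
      cx <- centers$x[b] + off[3]
      zr <- max(1, floor(cz - 4 * sigma[1]) + 1):min(nz, ceiling(cz + 4 * sigma[1]) + 1)
      yr <- max(1, floor(cy - 4 * sigma[2]) + 1):min(ny, ceiling(cy + 4 * sigma[2]) + 1)
      xr <- max(1, floor(cx - 4 * sigma[3]) + 1):min(nx, ceiling(cx + 4 * sigma[3]) + 1)
      gz <- exp(-((zr - 1 - cz)^2) / (2 * sigma[1]^2))
      gy <- exp(-((yr - 1 - cy)^2) / (2 * sigma[2]^2))
      gx <- exp(-((xr - 1 - cx)^2) / (2 * sigma[3]^2))
      vol[zr, yr, xr] <- vol[zr, yr, xr] +
        intensity * outer(outer(gz, gy), gx)
    }
    vol
  }
  list(channels = lapply(channel_offsets, render), centers = centers)
}

#' Simulated registration test pair
#'
#' Implements the simulation protocol used throughout the validation
#' machinery: filaments are generated on a canvas enlarged by `margin`
#' pixels per side, the known parameters are induced on the subject copy,
#' both channels are centrally cropped to `shape` (removing the margins
#' that fall outside the boundaries), and optionally both are attenuated by
#' `divisor` with independent noise realizations of standard deviation
#' `sigma` added to each channel.
#'
#' @param shape Final `c(nz, ny, nx)` (or `c(ny, nx)`).
#' @param params `affine_params7` to induce on the subject channel.
#' @param n_filaments Number of filaments.
#' @param seed RNG seed (controls both structure and noise).
#' @param margin Extra pixels per lateral side before cropping (default 16).
#' @param divisor Optional attenuation constant; `NULL` skips noise.
#' @param noise_kind `"gaussian"` or `"poisson"`.
#' @param sigma Noise standard deviation (default 10).
#' @return A list with arrays `ref` and `sub`.
#' @export
sim_registration_pair <- function(shape, params = affine_params(),
                                  n_filaments = 20, seed = NULL,
                                  margin = 16, divisor = NULL,
                                  noise_kind = "gaussian", sigma = 10) {
  if (!is.null(seed)) set.seed(seed)
  if (length(shape) == 2) shape <- c(1L, shape)
  big <- shape + c(0L, 2L * margin, 2L * margin)
  vol <- sim_filaments(big, n_filaments = n_filaments)
  sub <- induce_affine(vol, params)
  yr <- margin + seq_len(shape[2])
  xr <- margin + seq_len(shape[3])
  ref <- vol[, yr, xr, drop = FALSE]
  sub <- sub[, yr, xr, drop = FALSE]
  if (!is.null(divisor)) {
    ref <- add_noise(ref, divisor, noise_kind, sigma)
    sub <- add_noise(sub, divisor, noise_kind, sigma)
  }
  list(ref = ref, sub = sub)
}
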