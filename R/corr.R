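# Fourier-domain primitives: Gaussian-masked phase correlation, subpixel
# peak localization, and plain cross correlation.

# DFT sample frequencies in cycles/pixel, numpy-style ordering.
fft_freq <- function(n) {
  k <- seq_len(n) - 1L
  k[k >= ceiling(n / 2)] <- k[k >= ceiling(n / 2)] - n
  k / n
}

# Move the zero-frequency / zero-shift sample to index floor(n/2) (0-based)
# along every axis of a 2D or 3D array.
fftshift <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    c <- n %/% 2
    ((seq_len(n) - 1L - c) %% n) + 1L
  })
  do.call(`[`, c(list(x), idx))
}

#' Gaussian frequency-domain mask
#'
#' Builds the low-pass weight applied to the whitened spectra before phase
#' correlation.  The mask is a centered Gaussian in normalized frequency
#' (cycles/pixel) with standard deviation 0.2 times the Nyquist frequency
#' (0.5 cycles/pixel), i.e. sigma = 0.1 cycles/pixel per axis, attenuating
#' frequencies beyond the optical resolution limit.
#'
#' @param ny,nx Grid size in pixels; both must be at least 2.
#' @return An `ny` by `nx` matrix in unshifted (DC-first) frequency order,
#'   with value 1 at zero frequency.
#' @export
gaussian_frequency_mask <- function(ny, nx) {
  if (ny < 2 || nx < 2) stop("mask requires ny, nx >= 2")
  sigma <- 0.2 * 0.5
  fy <- fft_freq(ny)
  fx <- fft_freq(nx)
  outer(exp(-fy^2 / (2 * sigma^2)), exp(-fx^2 / (2 * sigma^2)))
}

#' Phase correlation of two images
#'
#' Whitens both spectra (amplitude normalized to one, with a small epsilon
#' guard against empty frequency bins), applies the Gaussian frequency mask,
#' multiplies the conjugate reference spectrum by the subject spectrum, and
#' inverse-transforms.  The resulting surface is shifted so that zero
#' displacement sits at the grid center `floor(n/2)` (0-based); the peak
#' offset from that center is the displacement of `sub` relative to `ref`.
#'
#' @param ref,sub Real matrices of identical shape (at least 8 pixels per
#'   side).
#' @return A list of class `corr_surface` with elements `surface` (real
#'   matrix) and `center` (0-based `c(cy, cx)` zero-shift position).
#' @export
phase_correlate <- function(ref, sub) {
  if (!identical(dim(ref), dim(sub))) stop("images must have the same shape")
  if (nrow(ref) < 8 || ncol(ref) < 8) stop("images must be at least 8x8")
  g <- gaussian_frequency_mask(nrow(ref), ncol(ref))
  f1 <- stats::fft(ref)
  f2 <- stats::fft(sub)
  eps1 <- 1e-12 * max(Mod(f1))
  eps2 <- 1e-12 * max(Mod(f2))
  if (eps1 == 0 || eps2 == 0) stop("cannot correlate an all-zero image")
  p1 <- g * f1 / (Mod(f1) + eps1)
  p2 <- g * f2 / (Mod(f2) + eps2)
  r <- Re(stats::fft(Conj(p1) * p2, inverse = TRUE)) / length(ref)
  structure(list(surface = fftshift(r),
                 center = c(nrow(ref) %/% 2, ncol(ref) %/% 2)),
            class = "corr_surface")
}

#' Subpixel peak localization on a correlation surface
#'
#' Finds the integer argmax (by default restricted to displacements within a
#' quarter of the image extent around zero shift, since larger shifts alias
#' under periodic boundaries) and refines each axis with a three-point
#' parabolic fit.
#'
#' @param surf A `corr_surface` from [phase_correlate()], or a plain matrix
#'   (zero shift then assumed at `floor(n/2)`).
#' @param max_shift Optional `c(dy, dx)` search radius in pixels; `NULL`
#'   means a quarter of the extent per axis.
#' @return A list with `shift` (`c(dy, dx)`, continuous pixels), `peak_value`
#'   (raw surface maximum), and `on_border` (logical; `TRUE` when the argmax
#'   hit the search border so no subpixel refinement was possible).
#' @export
locate_peak_subpixel <- function(surf, max_shift = NULL) {
  if (inherits(surf, "corr_surface")) {
    s <- surf$surface
    ctr <- surf$center
  } else {
    s <- surf
    ctr <- c(nrow(s) %/% 2, ncol(s) %/% 2)
  }
  ny <- nrow(s); nx <- ncol(s)
  if (is.null(max_shift)) max_shift <- c(ny, nx) / 4
  if (max(s) - min(s) <= 0) stop("flat correlation surface: no peak")
  iy <- (ctr[1] - floor(max_shift[1])):(ctr[1] + floor(max_shift[1])) + 1L
  ix <- (ctr[2] - floor(max_shift[2])):(ctr[2] + floor(max_shift[2])) + 1L
  iy <- iy[iy >= 1 & iy <= ny]
  ix <- ix[ix >= 1 & ix <= nx]
  win <- s[iy, ix, drop = FALSE]
  k <- arrayInd(which.max(win), dim(win))
  py <- iy[k[1]]; px <- ix[k[2]]
  peak <- s[py, px]
  on_border <- py == iy[1] || py == iy[length(iy)] ||
    px == ix[1] || px == ix[length(ix)]
  dy <- py - 1L - ctr[1]
  dx <- px - 1L - ctr[2]
  if (!on_border && py > 1 && py < ny && px > 1 && px < nx) {
    dy <- dy + parabolic_offset(s[py - 1L, px], peak, s[py + 1L, px])
    dx <- dx + parabolic_offset(s[py, px - 1L], peak, s[py, px + 1L])
  }
  list(shift = c(dy, dx), peak_value = peak, on_border = on_border)
}

# Vertex offset from a 3-point neighborhood (-1, ym), (0, y0), (1, yp).
# The Gaussian-masked correlation peak is Gaussian-shaped, so when all
# three samples are positive the parabola is fitted in the log domain
# (exact for a Gaussian peak, and free of the toward-integer bias a plain
# parabola shows at half-integer shifts); otherwise a plain parabolic fit
# is used.  Returns 0 for a degenerate (collinear/flat) neighborhood.
parabolic_offset <- function(ym, y0, yp) {
  if (ym > 0 && y0 > 0 && yp > 0 && y0 >= ym && y0 >= yp) {
    lm_ <- log(ym); l0 <- log(y0); lp <- log(yp)
    den <- lm_ - 2 * l0 + lp
    if (den < 0) return(max(min(0.5 * (lm_ - lp) / den, 0.5), -0.5))
  }
  den <- ym - 2 * y0 + yp
  if (den == 0) return(0)
  max(min(0.5 * (ym - yp) / den, 0.5), -0.5)
}

#' Plain 3D cross correlation shift
#'
#' Measures the overall 3D translation between two volumes by standard
#' (non-whitened) cross correlation computed in the Fourier domain, with
#' separable parabolic subpixel refinement.  Used as the final translation
#' polish after global alignment.  Volumes with fewer than 4 planes fall
#' back to 2D correlation of their z-maximum projections (dz = 0).
#'
#' @param vol1,vol2 Numeric arrays `(nz, ny, nx)` of identical shape.
#' @param max_shift Optional `c(dz, dy, dx)` search radius; `NULL` means a
#'   quarter of the extent per axis.
#' @return Numeric `c(dz, dy, dx)`: displacement of `vol2` relative to
#'   `vol1` in continuous pixels.
#' @export
cross_correlate_3d <- function(vol1, vol2, max_shift = NULL) {
  if (!identical(dim(vol1), dim(vol2))) stop("volumes must have the same shape")
  d <- dim(vol1)
  if (length(d) != 3) stop("expected 3D arrays")
  if (d[1] < 4) {
    p1 <- apply(vol1, c(2, 3), max)
    p2 <- apply(vol2, c(2, 3), max)
    f1 <- stats::fft(p1); f2 <- stats::fft(p2)
    r <- Re(stats::fft(Conj(f1) * f2, inverse = TRUE)) / length(p1)
    pk <- locate_peak_subpixel(fftshift(r), max_shift = max_shift[-1])
    return(c(0, pk$shift))
  }
  f1 <- stats::fft(vol1)
  f2 <- stats::fft(vol2)
  r <- Re(stats::fft(Conj(f1) * f2, inverse = TRUE)) / length(vol1)
  r <- fftshift(r)
  ctr <- d %/% 2
  if (is.null(max_shift)) max_shift <- d / 4
  idx <- lapply(1:3, function(a) {
    i <- (ctr[a] - floor(max_shift[a])):(ctr[a] + floor(max_shift[a])) + 1L
    i[i >= 1 & i <= d[a]]
  })
  win <- r[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  k <- arrayInd(which.max(win), dim(win))
  pos <- c(idx[[1]][k[1]], idx[[2]][k[2]], idx[[3]][k[3]])
  sh <- pos - 1L - ctr
  for (a in 1:3) {
    if (pos[a] > 1 && pos[a] < d[a]) {
      im <- pos; ip <- pos
      im[a] <- pos[a] - 1L; ip[a] <- pos[a] + 1L
      sh[a] <- sh[a] + parabolic_offset(r[im[1], im[2], im[3]],
                                        r[pos[1], pos[2], pos[3]],
                                        r[ip[1], ip[2], ip[3]])
    }
  }
  sh
}
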