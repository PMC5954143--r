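# Conversion of registration parameters to real-space deviations, the mean
# local-map error, and SNR estimation.

#' Edge deviation induced by a rotation
#'
#' Displacement of the image-edge coordinate `(nx, ny/2)` when rotated by
#' `theta_deg` about the image center `(nx/2, ny/2)` (0-based continuous
#' coordinates).  This is the edge-pixel rule used to express rotation as a
#' real-space shift.
#'
#' @param theta_deg Rotation angle, degrees (counter-clockwise in (x, y)).
#' @param shape `c(ny, nx)` in pixels.
#' @return A list with `rotated` (`c(x, y)` of the rotated coordinate) and
#'   `deviation_px` (`c(dx, dy)` = original minus rotated).
#' @export
rotation_edge_deviation <- function(theta_deg, shape) {
  ny <- shape[1]; nx <- shape[2]
  ctr <- c(nx / 2, ny / 2)
  th <- theta_deg * pi / 180
  edge <- c(nx, ny / 2)
  delta <- edge - ctr
  rot <- c(cos(th) * delta[1] - sin(th) * delta[2],
           sin(th) * delta[1] + cos(th) * delta[2]) + ctr
  list(rotated = rot, deviation_px = edge - rot)
}

#' Convert registration parameters to real-space deviations
#'
#' Translations convert directly via the pixel size.  Rotation and
#' magnification are expressed through the edge-pixel rule: the displacement
#' they induce at an image-edge coordinate — `(nx, ny/2)` for rotation and
#' for `m_x`, `(nx/2, ny)` for `m_y`, the last z-plane for `m_z` — relative
#' to the image center, times the pixel size.  The total is the Euclidean
#' vector sum over the seven per-parameter deviation vectors; `total_2d`
#' restricts the sum to the five lateral parameters.
#'
#' @param p An `affine_params7`.
#' @param shape `c(nz, ny, nx)` (or `c(ny, nx)` for 2D).
#' @param pixel_size_nm `c(x, y, z)` nm (scalar recycled).
#' @return A list of class `deviation_report`: `components` (named nm
#'   magnitudes for the seven parameters), `total`, `total_2d` (nm), and
#'   `pixel_size_nm`.
#' @export
params_to_deviation <- function(p, shape, pixel_size_nm = c(78, 78, 125)) {
  if (length(pixel_size_nm) == 1) pixel_size_nm <- rep(pixel_size_nm, 3)
  if (any(pixel_size_nm <= 0)) stop("pixel sizes must be positive")
  if (length(shape) == 2) shape <- c(1L, shape)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  px <- pixel_size_nm[1]; py <- pixel_size_nm[2]; pz <- pixel_size_nm[3]
  cx <- nx / 2; cy <- ny / 2; cz <- nz / 2
  rot <- rotation_edge_deviation(p$r_z, c(ny, nx))
  comp <- c(
    t_x = abs(p$t_x) * px,
    t_y = abs(p$t_y) * py,
    t_z = abs(p$t_z) * pz,
    m_x = abs(p$m_x - 1) * cx * px,
    m_y = abs(p$m_y - 1) * cy * py,
    m_z = abs(p$m_z - 1) * cz * pz,
    r_z = sqrt((rot$deviation_px[1] * px)^2 + (rot$deviation_px[2] * py)^2)
  )
  lateral <- c("t_x", "t_y", "m_x", "m_y", "r_z")
  structure(list(components = comp,
                 total = sqrt(sum(comp^2)),
                 total_2d = sqrt(sum(comp[lateral]^2)),
                 pixel_size_nm = pixel_size_nm),
            class = "deviation_report")
}

#' @export
print.deviation_report <- function(x, ...) {
  cat("Real-space registration deviation (nm):\n")
  print(round(x$components, 3))
  cat(sprintf("  total: %.3f nm (lateral 2D: %.3f nm)\n", x$total, x$total_2d))
  invisible(x)
}

# Interpret a shift field given as list(x =, y =) or an (ny, nx, 2) array
# with x first in the last dimension.
as_field <- function(f) {
  if (is.list(f)) return(list(x = f$x, y = f$y))
  if (length(dim(f)) == 3) return(list(x = f[, , 1], y = f[, , 2]))
  stop("shift field must be a list(x, y) or an (ny, nx, 2) array")
}

#' Mean local-map error
#'
#' Mean, over masked coordinates, of the Euclidean magnitude of the vector
#' difference between a recovered local shift map and the induced (true)
#' shift field.
#'
#' @param L,S Shift fields: lists with matrices `x` and `y` (pixels), or
#'   `(ny, nx, 2)` arrays.
#' @param mask Logical matrix of coordinates to include; default all.
#' @param pixel_size_nm Optional isotropic lateral pixel size; when given
#'   the error is returned in nm instead of pixels.
#' @return Mean error (pixels, or nm when `pixel_size_nm` is given).
#' @export
mean_local_error <- function(L, S, mask = NULL, pixel_size_nm = NULL) {
  L <- as_field(L); S <- as_field(S)
  if (!identical(dim(L$x), dim(S$x))) stop("fields must have the same shape")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(L$x), ncol(L$x))
  if (!any(mask)) stop("empty mask")
  err <- sqrt((L$x - S$x)^2 + (L$y - S$y)^2)
  e <- mean(err[mask])
  if (!is.null(pixel_size_nm)) e <- e * pixel_size_nm
  e
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing the between-class variance; used as
#' the automated stand-in for a visually chosen signal threshold.
#'
#' @param x Numeric vector, matrix or array of intensities.
#' @param levels Number of histogram bins (default 256).
#' @return The threshold intensity.
#' @export
otsu_threshold <- function(x, levels = 256) {
  x <- as.vector(x)
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  br <- seq(r[1], r[2], length.out = levels + 1)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  w <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- 0
  br[which.max(sb) + 1]
}

#' Estimate the signal-to-noise ratio
#'
#' SNR = mu / sigma, where mu is the mean of the pixels above an intensity
#' threshold (Otsu's threshold by default) and sigma the noise standard
#' deviation.
#'
#' @param img Numeric matrix or array.
#' @param sigma Noise standard deviation (> 0); the simulations use 10.
#' @param threshold Signal threshold; `NULL` picks Otsu's threshold.
#' @return The SNR (dimensionless).
#' @export
estimate_snr <- function(img, sigma = 10, threshold = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(threshold)) threshold <- otsu_threshold(img)
  above <- img[img > threshold]
  if (length(above) == 0) stop("no pixel above the threshold")
  mean(above) / sigma
}
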