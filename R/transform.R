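# The seven-parameter global transform and its application to images.
#
# Conventions used throughout the package:
#  * arrays are indexed (z, y, x); 2D images are (y, x) matrices;
#  * geometric coordinates are 0-based with the continuous image center at
#    n/2 per axis (so a 1024-wide image has center 512.0);
#  * a parameter set describes the *pull* (inverse) map used to resample a
#    subject channel onto the reference:
#        src_x = [cos(th)(x - x0) + sin(th)(y - y0)] / m_x + t_x + x0
#        src_y = [-sin(th)(x - x0) + cos(th)(y - y0)] / m_y + t_y + y0
#        src_z = (z - z0) / m_z + t_z + z0
#    with th = r_z in degrees and (x0, y0, z0) the image center.

#' Seven global registration parameters
#'
#' Translation in pixels, magnification as dimensionless zoom factors, and
#' rotation about the optical axis in degrees.  The identity is
#' `affine_params()`.  Magnifications are constrained to (0.8, 1.25) and
#' rotation to |r_z| < 10 degrees: the quadrisection estimator assumes small
#' displacements, and chromatic aberrations in fluorescence microscopes are
#' far smaller still.
#'
#' @param t_x,t_y,t_z Translation (pixels).
#' @param m_x,m_y,m_z Magnification (zoom factor).
#' @param r_z Rotation about the optical (z) axis, degrees.
#' @return An object of class `affine_params7`.
#' @export
affine_params <- function(t_x = 0, t_y = 0, t_z = 0,
                          m_x = 1, m_y = 1, m_z = 1, r_z = 0) {
  p <- list(t_x = t_x, t_y = t_y, t_z = t_z,
            m_x = m_x, m_y = m_y, m_z = m_z, r_z = r_z)
  if (any(!is.finite(unlist(p)))) stop("non-finite affine parameter")
  if (any(c(p$m_x, p$m_y, p$m_z) <= 0.8) || any(c(p$m_x, p$m_y, p$m_z) >= 1.25))
    stop("magnification outside (0.8, 1.25)")
  if (abs(p$r_z) >= 10) stop("|r_z| must be < 10 degrees")
  structure(p, class = "affine_params7")
}

#' @export
print.affine_params7 <- function(x, digits = 5, ...) {
  cat("Global registration parameters:\n")
  cat(sprintf("  translation (px):  t_x = %.*g, t_y = %.*g, t_z = %.*g\n",
              digits, x$t_x, digits, x$t_y, digits, x$t_z))
  cat(sprintf("  magnification:     m_x = %.*g, m_y = %.*g, m_z = %.*g\n",
              digits, x$m_x, digits, x$m_y, digits, x$m_z))
  cat(sprintf("  rotation (deg):    r_z = %.*g\n", digits, x$r_z))
  invisible(x)
}

#' @export
as.numeric.affine_params7 <- function(x, ...) {
  c(t_x = x$t_x, t_y = x$t_y, t_z = x$t_z,
    m_x = x$m_x, m_y = x$m_y, m_z = x$m_z, r_z = x$r_z)
}

# 2x2 pull matrix of the lateral part, rows/cols in (x, y) order.
affine_xy_matrix <- function(p) {
  th <- p$r_z * pi / 180
  rbind(c(cos(th) / p$m_x, sin(th) / p$m_x),
        c(-sin(th) / p$m_y, cos(th) / p$m_y))
}

# Recover (m_x, m_y, r_z) from a pull matrix of the above one-parameter
# family.  A composition of two such matrices carries a tiny residual skew
# (order theta * (m - 1)); it is dropped here and absorbed by the next
# estimation iteration.
affine_xy_decompose <- function(a) {
  th <- (atan2(a[1, 2], a[1, 1]) + atan2(-a[2, 1], a[2, 2])) / 2
  list(m_x = 1 / sqrt(a[1, 1]^2 + a[1, 2]^2),
       m_y = 1 / sqrt(a[2, 1]^2 + a[2, 2]^2),
       r_z = th * 180 / pi)
}

#' Compose two parameter sets
#'
#' `affine_compose(p, d)` is the transform equivalent to applying `p` and
#' then applying `d` to the result (both about the same image center), as
#' happens when an iteration measures a residual `d` on an already-warped
#' subject.
#'
#' @param p,d `affine_params7` objects.
#' @return An `affine_params7`.
#' @export
affine_compose <- function(p, d) {
  ap <- affine_xy_matrix(p)
  ad <- affine_xy_matrix(d)
  a <- ap %*% ad
  tv <- c(p$t_x, p$t_y) + as.vector(ap %*% c(d$t_x, d$t_y))
  dec <- affine_xy_decompose(a)
  az <- 1 / p$m_z
  affine_params(t_x = tv[1], t_y = tv[2],
                t_z = p$t_z + az * d$t_z,
                m_x = dec$m_x, m_y = dec$m_y,
                m_z = p$m_z * d$m_z,
                r_z = dec$r_z)
}

#' Invert a parameter set
#'
#' @param p An `affine_params7`.
#' @return The parameters whose application undoes `p` (about the same
#'   center).
#' @export
affine_invert <- function(p) {
  a <- affine_xy_matrix(p)
  ai <- solve(a)
  tv <- -as.vector(ai %*% c(p$t_x, p$t_y))
  dec <- affine_xy_decompose(ai)
  affine_params(t_x = tv[1], t_y = tv[2], t_z = -p$m_z * p$t_z,
                m_x = dec$m_x, m_y = dec$m_y, m_z = 1 / p$m_z,
                r_z = dec$r_z)
}

#' Dense affine coordinate map
#'
#' Evaluates the lateral pull map on every pixel of a plane: the returned
#' grids hold, for each output pixel, the 0-based source coordinate at which
#' the subject image is sampled.
#'
#' @param shape `c(ny, nx)` of the plane.
#' @param p An `affine_params7` (only the lateral part is used).
#' @param center Optional `c(x0, y0)` rotation/magnification center; default
#'   `c(nx/2, ny/2)`.
#' @return A list of class `dense_map` with matrices `map_y` and `map_x`.
#' @export
build_affine_map <- function(shape, p, center = NULL) {
  ny <- shape[1]; nx <- shape[2]
  if (is.null(center)) center <- c(nx / 2, ny / 2)
  th <- p$r_z * pi / 180
  x <- seq_len(nx) - 1 - center[1]
  y <- seq_len(ny) - 1 - center[2]
  # outer grids: rows y, cols x
  gx <- matrix(x, ny, nx, byrow = TRUE)
  gy <- matrix(y, ny, nx)
  map_x <- (cos(th) * gx + sin(th) * gy) / p$m_x + p$t_x + center[1]
  map_y <- (-sin(th) * gx + cos(th) * gy) / p$m_y + p$t_y + center[2]
  structure(list(map_y = map_y, map_x = map_x), class = "dense_map")
}

#' Resample an image plane at map coordinates
#'
#' Cubic (bicubic convolution) interpolation of `img` at the source
#' coordinates in `map`; coordinates outside the image yield the fill value
#' (0, the fluorescence background).
#'
#' @param img A numeric matrix.
#' @param map A `dense_map` (or list with `map_y`, `map_x` in 0-based
#'   pixels).
#' @param fill Fill value for out-of-range coordinates.
#' @return A matrix shaped like `map$map_y`.
#' @export
remap_image <- function(img, map, fill = 0) {
  if (!all(is.finite(map$map_y)) || !all(is.finite(map$map_x)))
    stop("non-finite map coordinates")
  remap_bicubic_cpp(img, map$map_y, map$map_x, fill)
}

#' Apply global parameters to a volume
#'
#' Two-pass warping with cubic interpolation: every ZY column stack is first
#' resampled along z by `(t_z, m_z)` about the z-center, then every XY plane
#' is warped by the lateral parameters about `(x0, y0)`.  Out-of-range
#' pixels are set to 0.
#'
#' @param vol A `(nz, ny, nx)` array or a `(ny, nx)` matrix.
#' @param p An `affine_params7`.
#' @param center Optional lateral center `c(x0, y0)`.
#' @return An array (or matrix) shaped like the input.
#' @export
apply_affine <- function(vol, p, center = NULL) {
  is2d <- is.matrix(vol)
  if (is2d) dim(vol) <- c(1L, dim(vol))
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (nz > 1 && (p$t_z != 0 || p$m_z != 1)) {
    cz <- nz / 2
    src_z <- (seq_len(nz) - 1 - cz) / p$m_z + p$t_z + cz
    vol <- resample_z_cubic_cpp(vol, d, src_z)
  }
  lateral <- p$t_x != 0 || p$t_y != 0 || p$m_x != 1 || p$m_y != 1 || p$r_z != 0
  if (lateral) {
    map <- build_affine_map(c(ny, nx), p, center)
    out <- vol
    for (z in seq_len(nz))
      out[z, , ] <- remap_bicubic_cpp(matrix(vol[z, , ], ny, nx),
                                      map$map_y, map$map_x, 0)
    vol <- out
  }
  if (is2d) dim(vol) <- d[2:3]
  vol
}
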