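# Quadrisection phase correlation: estimation of the seven global
# parameters from a reference multichannel image.

#' Select high-contrast z-sections
#'
#' Returns the contiguous range of z-sections, around the section of maximal
#' per-section variance, whose variance is at least half that maximum.
#' These are the sections worth projecting: out-of-focus planes contribute
#' little but blur.
#'
#' @param vol A `(nz, ny, nx)` array.
#' @param frac Fraction of the maximum per-section variance a section must
#'   reach (default 0.5).
#' @return Integer vector of section indices (contiguous, never empty).
#' @export
select_contrast_sections <- function(vol, frac = 0.5) {
  nz <- dim(vol)[1]
  v <- vapply(seq_len(nz), function(z) stats::var(as.vector(vol[z, , ])), 0)
  if (max(v) == 0) stop("no contrast: all sections are constant")
  k <- which.max(v)
  ok <- v >= frac * max(v)
  lo <- k
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- k
  while (hi < nz && ok[hi + 1]) hi <- hi + 1
  lo:hi
}

#' Maximum-intensity projection
#'
#' @param vol A `(nz, ny, nx)` array.
#' @param axis `"z"` (projects to an XY image, rows y / cols x) or `"x"`
#'   (projects to a ZY image, rows z / cols y).
#' @param sections Indices along the projected axis to include; default all.
#' @return A matrix.
#' @export
project_max <- function(vol, axis = c("z", "x"), sections = NULL) {
  axis <- match.arg(axis)
  d <- dim(vol)
  n <- if (axis == "z") d[1] else d[3]
  if (is.null(sections)) sections <- seq_len(n)
  if (length(sections) == 0) stop("empty section range")
  if (axis == "z") {
    sub <- vol[sections, , , drop = FALSE]
    apply(sub, c(2, 3), max)
  } else {
    sub <- vol[, , sections, drop = FALSE]
    apply(sub, c(1, 2), max)
  }
}

#' Per-quadrant displacement vectors
#'
#' Splits both images into four quadrants at the image center and measures
#' the phase-correlation shift of the subject relative to the reference in
#' each.  Vectors are reported in (x, y) order together with the quadrant
#' centers relative to the continuous image center.
#'
#' Quadrants are labelled `a` (+x, +y), `b` (-x, +y), `c` (-x, -y) and
#' `d` (+x, -y), so `(a, c)` and `(b, d)` are the diagonal pairs.
#'
#' @param ref,sub Matrices of identical shape.
#' @param peak_floor Minimum admissible correlation peak; below it the
#'   quadrant is deemed featureless and an error is raised.
#' @return A list of class `quadrant_vectors`: `a`, `b`, `c`, `d` (each
#'   `c(x, y)` pixels) and `centers` (4 x 2 matrix of quadrant centers).
#' @export
measure_quadrant_vectors <- function(ref, sub, peak_floor = 1e-4) {
  if (!identical(dim(ref), dim(sub))) stop("images must have the same shape")
  ny <- nrow(ref); nx <- ncol(ref)
  cy <- ny %/% 2; cx <- nx %/% 2
  rows <- list(hi = (cy + 1L):ny, lo = 1L:cy)  # +y / -y halves
  cols <- list(hi = (cx + 1L):nx, lo = 1L:cx)  # +x / -x halves
  quads <- list(a = c("hi", "hi"), b = c("hi", "lo"),
                c = c("lo", "lo"), d = c("lo", "hi"))
  out <- list()
  for (nm in names(quads)) {
    ri <- rows[[quads[[nm]][1]]]
    ci <- cols[[quads[[nm]][2]]]
    pk <- locate_peak_subpixel(phase_correlate(ref[ri, ci], sub[ri, ci]))
    if (pk$peak_value < peak_floor)
      stop(sprintf("no detectable correlation peak in quadrant '%s'", nm))
    out[[nm]] <- c(pk$shift[2], pk$shift[1])  # (x, y)
  }
  qx <- nx / 4; qy <- ny / 4
  out$centers <- rbind(a = c(qx, qy), b = c(-qx, qy),
                       c = c(-qx, -qy), d = c(qx, -qy))
  class(out) <- "quadrant_vectors"
  out
}

#' Decompose quadrant vectors into translation, rotation and magnification
#'
#' Summing a diagonal pair cancels the rotation and magnification parts and
#' leaves (twice) the translation; the half-difference of a pair, taken at
#' the pair's quadrant center, carries the rotation (tangential) and
#' magnification (radial) components.  The rotation angle is the arctangent
#' of the tangential displacement over the quadrant-center radius, averaged
#' over both diagonal pairs; the per-axis magnification factor is
#' `(M + c) / c` with `M` the radial displacement linearly extrapolated to
#' the image-edge coordinate `c`.
#'
#' @param qv A `quadrant_vectors` object.
#' @param image_shape `c(ny, nx)` of the quadrisected image.
#' @return A list with `t` (`c(x, y)` pixels), `r_z` (degrees) and `m`
#'   (`c(x, y)` zoom factors).
#' @export
decompose_quadrants <- function(qv, image_shape) {
  qx <- image_shape[2] / 4
  qy <- image_shape[1] / 4
  tr <- ((qv$a + qv$c) / 2 + (qv$b + qv$d) / 2) / 2
  h1 <- (qv$a - qv$c) / 2        # at (+qx, +qy)
  h2 <- (qv$b - qv$d) / 2        # at (-qx, +qy)
  # First-order field of the pull map about the center:
  #   d(p) = ((1/m_x - 1) p_x + th p_y,  -th p_x + (1/m_y - 1) p_y)
  th1 <- (h1[1] + h2[1]) / (2 * qy)
  th2 <- (h2[2] - h1[2]) / (2 * qx)
  if (abs(th1 - th2) > max(0.2 * max(abs(th1), abs(th2)), 2e-3))
    warning("diagonal pairs give inconsistent rotation estimates; using mean")
  r_z <- atan((th1 + th2) / 2) * 180 / pi
  # Radial residual displacement per unit radius; extrapolated to the edge
  # coordinate c = 2q it gives the edge shift M with M/c = alpha, and the
  # magnification factor follows as c / (M + c) = 1 / (1 + alpha): the
  # measured residual lives in the resampling (pull) frame, so the content
  # magnification is its reciprocal.
  alpha_x <- (h1[1] - h2[1]) / (2 * qx)
  alpha_y <- (h1[2] + h2[2]) / (2 * qy)
  list(t = as.vector(tr), r_z = r_z,
       m = c(1 / (1 + alpha_x), 1 / (1 + alpha_y)))
}

#' Estimate the seven global registration parameters
#'
#' Iterates quadrisection phase correlation on maximum-intensity
#' projections: the XY projection yields (t_x, t_y, m_x, m_y, r_z), the ZY
#' projection (t_z, m_z); after each pass the accumulated parameters are
#' re-applied to the original subject and the residual re-measured, until
#' the per-iteration change is below `tol_nm` in real space or `max_iter`
#' iterations are reached.  Stacks with fewer than 32 z-sections (too few
#' planes to quadrisect vertically with stable statistics) fall back to
#' plain phase correlation for the z-translation only, and stacks under 8
#' sections leave the axial correction entirely to the final polish.  A
#' final plain 3D cross correlation polishes the overall translation.
#'
#' @param ref_vol,sub_vol `(nz, ny, nx)` arrays (or `(ny, nx)` matrices) of
#'   the reference and subject channels.
#' @param pixel_size_nm `c(x, y, z)` pixel size in nm (z ignored for 2D).
#' @param max_iter Maximum number of iterations (default 20).
#' @param tol_nm Real-space convergence tolerance in nm (default 1).
#' @return A list of class `global_fit`: `params` (an `affine_params7`),
#'   `converged`, `z_fallback` (logical: quadrisection in z was not
#'   possible), and `iterations` (data frame logging the per-iteration
#'   accumulated parameters and the real-space step size).
#' @export
estimate_global <- function(ref_vol, sub_vol,
                            pixel_size_nm = c(78, 78, 125),
                            max_iter = 20, tol_nm = 1) {
  if (is.matrix(ref_vol)) dim(ref_vol) <- c(1L, dim(ref_vol))
  if (is.matrix(sub_vol)) dim(sub_vol) <- c(1L, dim(sub_vol))
  if (!identical(dim(ref_vol), dim(sub_vol)))
    stop("reference and subject must have the same shape")
  d <- dim(ref_vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (length(pixel_size_nm) == 1) pixel_size_nm <- rep(pixel_size_nm, 3)
  zsec <- if (nz > 1) select_contrast_sections(ref_vol) else 1L
  do_z <- nz >= 8   # below 8 sections the final 3D polish handles t_z alone
  z_quad <- nz >= 32
  # per-iteration residuals are small by construction; clamping them keeps a
  # noise-corrupted measurement from throwing the accumulation out of range
  clamp <- function(v, lim) max(min(v, lim), -lim)
  clamp_m <- function(m, lim) max(min(m, 1 + lim), 1 - lim)
  # Static support: if either channel already carries fully-zero border
  # planes (e.g. the margins of a previously corrected image), blank the
  # same planes in the other channel, so re-measuring a corrected image is
  # not biased by its dead margins.
  axis_support <- function(a, b) {
    rng <- function(v) {
      i <- which(v > 0)
      out <- rep(0, length(v))
      if (length(i)) out[min(i):max(i)] <- 1
      out
    }
    prof <- function(vol, ax) apply(abs(vol), ax, max)
    list(z = rng(pmin(prof(a, 1), prof(b, 1))),
         y = rng(pmin(prof(a, 2), prof(b, 2))),
         x = rng(pmin(prof(a, 3), prof(b, 3))))
  }
  sup <- axis_support(ref_vol, sub_vol)
  static3 <- outer(sup$z, outer(sup$y, sup$x))
  # Valid-region mask of the pull map for the current parameters: the warp
  # zero-fills pixels pulled from outside the subject, so the same pixels
  # are blanked in the reference before correlating; an asymmetric support
  # would otherwise bias the quadrant peaks by a few hundredths of a pixel.
  mask3d <- function(p) {
    m <- build_affine_map(c(ny, nx), p)
    mxy <- (m$map_x >= 1 & m$map_x <= nx - 2 &
              m$map_y >= 1 & m$map_y <= ny - 2) * 1
    if (nz == 1) return(array(mxy, c(1L, ny, nx)) * static3)
    src_z <- (seq_len(nz) - 1 - nz / 2) / p$m_z + p$t_z + nz / 2
    zv <- (src_z >= 1 & src_z <= nz - 2) * 1
    outer(zv, mxy) * static3
  }
  p <- affine_params()
  log <- list()
  converged <- FALSE
  warped <- sub_vol
  for (it in seq_len(max_iter)) {
    msk <- mask3d(p)
    ref_xy <- project_max(ref_vol * msk, "z", zsec)
    sub_xy <- project_max(warped * msk, "z", zsec)
    qv <- measure_quadrant_vectors(ref_xy, sub_xy)
    dec <- decompose_quadrants(qv, c(ny, nx))
    d_lat <- affine_params(t_x = clamp(dec$t[1], nx / 4),
                           t_y = clamp(dec$t[2], ny / 4),
                           m_x = clamp_m(dec$m[1], 0.05),
                           m_y = clamp_m(dec$m[2], 0.05),
                           r_z = clamp(dec$r_z, 3))
    p_prev <- p
    p <- compose_guarded(p, d_lat)
    d_ax <- affine_params()
    if (do_z) {
      warped <- apply_affine(sub_vol, p)
      msk <- mask3d(p)
      ref_zy <- project_max(ref_vol * msk, "x")
      sub_zy <- project_max(warped * msk, "x")
      if (z_quad) {
        qvz <- measure_quadrant_vectors(ref_zy, sub_zy)
        decz <- decompose_quadrants(qvz, dim(ref_zy))
        # ZY image: rows are z, columns are y; keep only the z components
        d_ax <- affine_params(t_z = clamp(decz$t[2], nz / 4),
                              m_z = clamp_m(decz$m[2], 0.05))
      } else {
        pk <- locate_peak_subpixel(phase_correlate(ref_zy, sub_zy))
        d_ax <- affine_params(t_z = clamp(pk$shift[1], nz / 4))
      }
      p <- compose_guarded(p, d_ax)
    }
    warped <- apply_affine(sub_vol, p)
    step <- affine_params(t_x = d_lat$t_x, t_y = d_lat$t_y, t_z = d_ax$t_z,
                          m_x = d_lat$m_x, m_y = d_lat$m_y, m_z = d_ax$m_z,
                          r_z = d_lat$r_z)
    step_nm <- params_to_deviation(step, c(nz, ny, nx), pixel_size_nm)$total
    log[[it]] <- c(as.numeric(p), step_nm = step_nm)
    if (step_nm < tol_nm) {
      converged <- TRUE
      break
    }
  }
  # final overall translation polish by plain 3D cross correlation
  msk <- mask3d(p)
  s <- cross_correlate_3d(ref_vol * msk, warped * msk)
  p <- affine_compose(p, affine_params(t_x = s[3], t_y = s[2], t_z = s[1]))
  it_log <- as.data.frame(do.call(rbind, log))
  structure(list(params = p, converged = converged,
                 z_fallback = do_z && !z_quad,
                 iterations = it_log,
                 shape = c(nz, ny, nx),
                 pixel_size_nm = pixel_size_nm),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf("Quadrisection global fit (%s in %d iteration%s%s)\n",
              if (x$converged) "converged" else "not converged",
              nrow(x$iterations),
              if (nrow(x$iterations) == 1) "" else "s",
              if (x$z_fallback) "; z translation-only fallback" else ""))
  print(x$params)
  invisible(x)
}

# Compose p with a measured residual d, falling back to p unchanged when
# the accumulation would leave the admissible parameter range (a sign the
# measurement was noise-corrupted, not a real chromatic shift).
compose_guarded <- function(p, d) {
  out <- tryCatch(affine_compose(p, d), error = function(e) NULL)
  if (is.null(out)) {
    warning("discarded an out-of-range iteration update")
    p
  } else out
}
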