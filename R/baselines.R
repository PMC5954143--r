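# Comparison estimators: log-polar phase correlation and simplex
# optimization of the Pearson correlation.  Both operate on 2D images and
# estimate the five lateral parameters.

# Log-polar resampling of an image about its center: rows are rotation
# angles in [0, pi), columns are radii base^j, cubic interpolation.
logpolar_transform <- function(img, base = 1.012, n_angles = NULL) {
  ny <- nrow(img); nx <- ncol(img)
  if (is.null(n_angles)) n_angles <- max(ny, nx)
  ctr <- c(nx / 2, ny / 2)
  rmax <- sqrt(sum(c(nx, ny)^2)) / 2
  n_rad <- floor(log(rmax) / log(base))
  th <- (seq_len(n_angles) - 1) * pi / n_angles
  r <- base^(seq_len(n_rad) - 1)
  map_x <- outer(cos(th), r) + ctr[1]
  map_y <- outer(sin(th), r) + ctr[2]
  remap_bicubic_cpp(img, map_y, map_x, 0)
}

#' Log-polar rotation/magnification estimator
#'
#' The classical baseline: translation is first measured by plain
#' full-frame phase correlation; both images are then log-polar transformed
#' about the center (rotation angles spanning \[0, pi), radial sampling with
#' log base 1.012) and the phase-correlation peak of the transformed pair
#' gives the rotation angle and a single isotropic magnification factor
#' (the transform cannot separate the X and Y axes).  The cycle is iterated
#' until the update is below `tol_nm` in real space or `max_iter` rounds.
#'
#' @param ref,sub Matrices of identical shape.
#' @param pixel_size_nm Lateral pixel size (nm), for the convergence test.
#' @param base Radial log base (default 1.012).
#' @param max_iter Maximum iterations (default 20).
#' @param tol_nm Real-space convergence tolerance (default 1 nm).
#' @return A list of class `baseline_fit`: `params` (an `affine_params7`
#'   with `m_x == m_y`), `converged`, and `iterations`.
#' @export
logpolar_estimate <- function(ref, sub, pixel_size_nm = 78, base = 1.012,
                              max_iter = 20, tol_nm = 1) {
  if (!identical(dim(ref), dim(sub))) stop("images must have the same shape")
  if (stats::var(as.vector(ref)) == 0 || stats::var(as.vector(sub)) == 0)
    stop("degenerate (constant) image")
  ny <- nrow(ref); nx <- ncol(ref)
  n_angles <- max(ny, nx)
  lp_ref <- logpolar_transform(ref, base, n_angles)
  p <- affine_params()
  warped <- sub
  converged <- FALSE
  log <- list()
  for (it in seq_len(max_iter)) {
    pk <- locate_peak_subpixel(phase_correlate(ref, warped))
    d_t <- affine_params(t_x = pk$shift[2], t_y = pk$shift[1])
    p <- affine_compose(p, d_t)
    warped <- apply_affine(sub, p)
    lp_sub <- logpolar_transform(warped, base, n_angles)
    pk2 <- locate_peak_subpixel(phase_correlate(lp_ref, lp_sub),
                                max_shift = c(n_angles / 4, 40))
    # the angular/radial shift of the log-polar pair gives the content
    # rotation and scale; the pull-map parameters are their inverses
    dth <- -pk2$shift[1] * 180 / n_angles   # degrees per angular bin
    dmag <- base^(-pk2$shift[2])
    d_rm <- affine_params(r_z = max(min(dth, 3), -3),
                          m_x = max(min(dmag, 1.05), 0.95),
                          m_y = max(min(dmag, 1.05), 0.95))
    p <- tryCatch(affine_compose(p, d_rm), error = function(e) p)
    warped <- apply_affine(sub, p)
    step <- affine_params(t_x = d_t$t_x, t_y = d_t$t_y, m_x = d_rm$m_x,
                          m_y = d_rm$m_y, r_z = d_rm$r_z)
    step_nm <- params_to_deviation(step, c(ny, nx),
                                   pixel_size_nm)$total_2d
    log[[it]] <- c(as.numeric(p), step_nm = step_nm)
    if (step_nm < tol_nm) {
      converged <- TRUE
      break
    }
  }
  structure(list(params = p, converged = converged,
                 iterations = as.data.frame(do.call(rbind, log))),
            class = "baseline_fit")
}

# Pearson correlation between reference and a warped subject after
# removing `margin` boundary pixels.
pearson_after_warp <- function(ref, sub, p, margin) {
  w <- apply_affine(sub, p)
  ny <- nrow(ref); nx <- ncol(ref)
  ri <- (margin + 1):(ny - margin)
  ci <- (margin + 1):(nx - margin)
  stats::cor(as.vector(ref[ri, ci]), as.vector(w[ri, ci]))
}

# Scan a single parameter, fit a 6th-order polynomial to the Pearson
# correlations, and return the argmax within the scanned range.
scan_argmax <- function(vals, cors) {
  fit <- stats::lm(cors ~ stats::poly(vals, 6, raw = TRUE))
  fine <- seq(min(vals), max(vals), length.out = 2001)
  pred <- stats::predict(fit, data.frame(vals = fine))
  fine[which.max(pred)]
}

#' Simplex (Nelder-Mead) estimator
#'
#' The optimization baseline: initial translation from full-frame phase
#' correlation; an initial rotation guess from scanning -0.4 to 0.4 degrees
#' in 0.02-degree steps and fitting the Pearson correlations with a
#' 6th-order polynomial; per-axis magnification guesses likewise from a
#' 0.98 to 1.02 scan in steps of 0.005; then downhill-simplex minimization
#' of 1/Pearson after warping and removing image margins.
#'
#' @param ref,sub Matrices of identical shape.
#' @param margin Boundary pixels removed before computing the correlation
#'   (default 16).
#' @param maxit Simplex iteration budget (default 400).
#' @return A list of class `baseline_fit` with `params`, `converged`, and
#'   `value` (the final 1/Pearson).
#' @export
simplex_estimate <- function(ref, sub, margin = 16, maxit = 400) {
  if (!identical(dim(ref), dim(sub))) stop("images must have the same shape")
  pk <- locate_peak_subpixel(phase_correlate(ref, sub))
  t0 <- c(pk$shift[2], pk$shift[1])
  base_t <- affine_params(t_x = t0[1], t_y = t0[2])
  angles <- seq(-0.4, 0.4, by = 0.02)
  cors <- vapply(angles, function(a)
    pearson_after_warp(ref, sub, affine_params(t_x = t0[1], t_y = t0[2],
                                               r_z = a), margin), 0)
  r0 <- scan_argmax(angles, cors)
  mags <- seq(0.98, 1.02, by = 0.005)
  cors_mx <- vapply(mags, function(m)
    pearson_after_warp(ref, sub, affine_params(t_x = t0[1], t_y = t0[2],
                                               r_z = r0, m_x = m), margin), 0)
  mx0 <- scan_argmax(mags, cors_mx)
  cors_my <- vapply(mags, function(m)
    pearson_after_warp(ref, sub, affine_params(t_x = t0[1], t_y = t0[2],
                                               r_z = r0, m_y = m), margin), 0)
  my0 <- scan_argmax(mags, cors_my)
  cost <- function(v) {
    p <- tryCatch(affine_params(t_x = v[1], t_y = v[2],
                                m_x = v[3], m_y = v[4], r_z = v[5]),
                  error = function(e) NULL)
    if (is.null(p)) return(1e6)
    r <- pearson_after_warp(ref, sub, p, margin)
    if (!is.finite(r) || r <= 0) return(1e6)
    1 / r
  }
  opt <- stats::optim(c(t0, mx0, my0, r0), cost, method = "Nelder-Mead",
                      control = list(maxit = maxit,
                                     parscale = c(1, 1, 0.01, 0.01, 0.1)))
  structure(list(params = affine_params(t_x = opt$par[1], t_y = opt$par[2],
                                        m_x = opt$par[3], m_y = opt$par[4],
                                        r_z = opt$par[5]),
                 converged = opt$convergence == 0,
                 value = opt$value),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("Baseline estimator fit (%s)\n",
              if (x$converged) "converged" else "not converged"))
  print(x$params)
  invisible(x)
}
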