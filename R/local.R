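# Multi-level elastic refinement: per-tile phase-correlation translations
# with variance gating and peak quality control, gap filling, Fourier
# upsampling to a dense map, and iteration with window halving.

#' Image-level variance threshold
#'
#' The gate below which a tile is considered too featureless to correlate:
#' `c * var(ref) * var(sub)`, with `c = 0.1` an empirically determined
#' constant.  The product form presumes comparably scaled images; the local
#' pipeline normalizes both channels to unit maximum before gating.
#'
#' @param ref,sub Matrices of identical shape.
#' @param c Gate constant (default 0.1).
#' @return The threshold (same units as the tile variances).
#' @export
variance_threshold <- function(ref, sub, c = 0.1) {
  if (!identical(dim(ref), dim(sub))) stop("images must have the same shape")
  c * stats::var(as.vector(ref)) * stats::var(as.vector(sub))
}

#' Central-quarter tile variance
#'
#' Mean of the variances of the two channels' central quarter regions (half
#' width per axis).  Only the tile center carries the pure translation of
#' the region -- its periphery mixes in the shifts of adjacent regions -- so
#' only the center votes on whether the tile has usable contrast.
#'
#' @param tile_ref,tile_sub Matrices of identical shape, at least 8 px per
#'   side.
#' @return The gating variance.
#' @export
tile_variance <- function(tile_ref, tile_sub) {
  if (!identical(dim(tile_ref), dim(tile_sub)))
    stop("tiles must have the same shape")
  if (nrow(tile_ref) < 8 || ncol(tile_ref) < 8)
    stop("tiles must be at least 8 px per side")
  ny <- nrow(tile_ref); nx <- ncol(tile_ref)
  ri <- (floor(ny / 4) + 1L):(floor(ny / 4) + floor(ny / 2))
  ci <- (floor(nx / 4) + 1L):(floor(nx / 4) + floor(nx / 2))
  (stats::var(as.vector(tile_ref[ri, ci])) +
     stats::var(as.vector(tile_sub[ri, ci]))) / 2
}

#' Measure per-tile translations
#'
#' Splits the images into `n_tiles x n_tiles` elements and measures the
#' phase-correlation shift of the subject relative to the reference in each
#' element, for the base tiling plus the three half-shifted tilings (start
#' coordinates offset by half a window in x, y, or both), yielding a
#' `2 n_tiles x 2 n_tiles` grid.  Tiles whose central-quarter variance
#' falls below [variance_threshold()], whose correlation peak is at most
#' `peak_threshold`, or which are truncated below 75% of the nominal window
#' at the image border, are marked invalid.
#'
#' @param ref,sub Matrices of identical shape.
#' @param n_tiles Elements per axis of the base tiling (default 4).
#' @param c Variance-gate constant (default 0.1).
#' @param peak_threshold Minimum phase-correlation peak value (default
#'   0.02).
#' @return A list of class `local_shift_map`: matrices `tx`, `ty`
#'   (pixels), logical `valid`, `window` (`c(wy, wx)` nominal tile size),
#'   `stride` (`c(sy, sx)` grid spacing), and `n_tiles`.
#' @export
measure_tile_shifts <- function(ref, sub, n_tiles = 4, c = 0.1,
                                peak_threshold = 0.02, max_shift = 8,
                                window_sigma = 0.25) {
  if (!identical(dim(ref), dim(sub))) stop("images must have the same shape")
  ny <- nrow(ref); nx <- ncol(ref)
  wy <- floor(ny / n_tiles); wx <- floor(nx / n_tiles)
  if (wy < 8 || wx < 8) stop("tiles smaller than 8 px: too many tiles")
  # comparable intensity scale for the variance gate
  sc_r <- max(abs(ref)); sc_s <- max(abs(sub))
  if (sc_r == 0 || sc_s == 0) stop("no usable contrast in the images")
  refn <- ref / sc_r; subn <- sub / sc_s
  v_thr <- variance_threshold(refn, subn, c)
  # Gaussian taper centered on the tile: concentrates the measurement on
  # the tile center (whose shift the element is meant to carry -- the same
  # rationale as the central-quarter variance gate) and suppresses the
  # wrap-around artifacts of the periodic FFT; the whitened correlation
  # peak height is unaffected, so the 0.02 quality gate keeps its meaning
  taper <- if (is.finite(window_sigma)) {
    wf <- function(n) exp(-0.5 * ((seq_len(n) - (n + 1) / 2) /
                                    (window_sigma * n))^2)
    outer(wf(wy), wf(wx))
  } else NULL
  m <- 2L * n_tiles
  tx <- matrix(NA_real_, m, m)
  ty <- matrix(NA_real_, m, m)
  valid <- matrix(FALSE, m, m)
  truncated <- matrix(FALSE, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      y0 <- (i - 1L) * wy %/% 2L
      x0 <- (j - 1L) * wx %/% 2L
      ri <- (y0 + 1L):min(y0 + wy, ny)
      ci <- (x0 + 1L):min(x0 + wx, nx)
      if (length(ri) < 0.75 * wy || length(ci) < 0.75 * wx) {
        truncated[i, j] <- TRUE
        next
      }
      tr <- refn[ri, ci]; ts <- subn[ri, ci]
      if (tile_variance(tr, ts) < v_thr) next
      if (!is.null(taper)) {
        tw <- taper[seq_along(ri), seq_along(ci)]
        tr <- tr * tw; ts <- ts * tw
      }
      pk <- tryCatch(locate_peak_subpixel(phase_correlate(tr, ts),
                                          max_shift = c(max_shift, max_shift)),
                     error = function(e) NULL)
      if (is.null(pk) || pk$peak_value <= peak_threshold) next
      tx[i, j] <- pk$shift[2]
      ty[i, j] <- pk$shift[1]
      valid[i, j] <- TRUE
    }
  }
  if (!any(valid)) stop("no usable contrast: all tiles gated out")
  structure(list(tx = tx, ty = ty, valid = valid, truncated = truncated,
                 window = c(wy, wx), stride = c(wy / 2, wx / 2),
                 n_tiles = n_tiles),
            class = "local_shift_map")
}

#' Fill gated-out tiles of a shift map
#'
#' Invalid tiles are filled with a mean filter that only alters empty
#' entries: in rounds of growing square windows (3x3, then 5x5, ...), an
#' empty tile takes the mean of the tiles already valid (measured, or
#' filled in an earlier round) inside the window.  Valid tiles are never
#' modified.
#'
#' @param map A `local_shift_map` with at least one valid tile.
#' @return The map with all tiles filled; the original `valid` mask is
#'   preserved in `measured`.
#' @export
fill_empty <- function(map) {
  if (!any(map$valid)) stop("cannot fill a map with no valid tile")
  m <- nrow(map$valid)
  tx <- map$tx; ty <- map$ty; valid <- map$valid
  trunc <- if (is.null(map$truncated)) matrix(FALSE, m, m) else map$truncated
  k <- 1L
  while (!all(valid | trunc)) {
    snap_tx <- tx; snap_ty <- ty; snap_valid <- valid
    filled_any <- FALSE
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (valid[i, j] || trunc[i, j]) next
        ri <- max(1L, i - k):min(m, i + k)
        ci <- max(1L, j - k):min(m, j + k)
        nb <- snap_valid[ri, ci] & !trunc[ri, ci]
        if (any(nb)) {
          tx[i, j] <- mean(snap_tx[ri, ci][nb])
          ty[i, j] <- mean(snap_ty[ri, ci][nb])
          valid[i, j] <- TRUE
          filled_any <- TRUE
        }
      }
    }
    if (!filled_any) k <- k + 1L
  }
  # border slots whose tiles are truncated by the image edge never carry a
  # measurement; extrapolate them linearly from the interior so the global
  # Fourier interpolant is not dragged toward interior values at the edge
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (!trunc[i, j]) next
    jj <- max(1L, j - 1L):min(m, j + 1L)
    ii <- max(1L, i - 1L):min(m, i + 1L)
    if (i > 2 && !any(trunc[i - 1, jj]) && !any(trunc[i - 2, jj])) {
      # extrapolate from laterally averaged neighbors: keeps the edge slope
      # without doubling the single-tile measurement noise
      tx[i, j] <- 2 * mean(tx[i - 1, jj]) - mean(tx[i - 2, jj])
      ty[i, j] <- 2 * mean(ty[i - 1, jj]) - mean(ty[i - 2, jj])
    } else if (j > 2 && !any(trunc[ii, j - 1]) && !any(trunc[ii, j - 2])) {
      tx[i, j] <- 2 * mean(tx[ii, j - 1]) - mean(tx[ii, j - 2])
      ty[i, j] <- 2 * mean(ty[ii, j - 1]) - mean(ty[ii, j - 2])
    } else {
      nb <- which(!trunc, arr.ind = TRUE)
      d2 <- (nb[, 1] - i)^2 + (nb[, 2] - j)^2
      k0 <- nb[which.min(d2), ]
      tx[i, j] <- tx[k0[1], k0[2]]
      ty[i, j] <- ty[k0[1], k0[2]]
    }
    valid[i, j] <- TRUE
  }
  out <- map
  out$tx <- tx; out$ty <- ty
  out$measured <- map$valid
  out$valid <- valid
  out
}

# Fourier zero-padding interpolation of a small grid to shape (ny, nx),
# with an optional spatial offset (pixels) of the first grid sample.
fourier_upsample <- function(g, ny, nx, offset = c(0, 0)) {
  gy <- nrow(g); gx <- ncol(g)
  fg <- stats::fft(g)
  # split Nyquist bins (even sizes) to keep the interpolant real and flat
  # for constant input
  big <- matrix(0 + 0i, ny, nx)
  ky <- round(fft_freq(gy) * gy)
  kx <- round(fft_freq(gx) * gx)
  wy <- rep(1, gy); wx <- rep(1, gx)
  if (gy %% 2 == 0) wy[gy %/% 2 + 1] <- 0.5
  if (gx %% 2 == 0) wx[gx %/% 2 + 1] <- 0.5
  place <- function(k, n) ifelse(k >= 0, k, n + k) + 1L
  for (i in seq_len(gy)) {
    for (j in seq_len(gx)) {
      kset_y <- if (gy %% 2 == 0 && i == gy %/% 2 + 1) c(ky[i], -ky[i]) else ky[i]
      kset_x <- if (gx %% 2 == 0 && j == gx %/% 2 + 1) c(kx[j], -kx[j]) else kx[j]
      for (kyy in kset_y) for (kxx in kset_x) {
        ph <- exp(-2i * pi * (kyy * offset[1] / ny + kxx * offset[2] / nx))
        big[place(kyy, ny), place(kxx, nx)] <-
          big[place(kyy, ny), place(kxx, nx)] +
          fg[i, j] * wy[i] * wx[j] * ph
      }
    }
  }
  Re(stats::fft(big, inverse = TRUE)) / (gy * gx)
}

#' Upsample a tile-shift grid to a dense map component
#'
#' Frequency-domain zero-padding interpolation of each shift component to
#' the full image size (Fourier transform, pad, inverse transform),
#' rescaled so a constant grid stays constant, and phase-shifted so grid
#' samples land on the tile centers.
#'
#' @param map A filled `local_shift_map`.
#' @param shape `c(ny, nx)` of the target image.
#' @return A list with matrices `x` and `y`: the dense local shift field
#'   L(x, y) in pixels.
#' @export
upsample_map <- function(map, shape) {
  if (any(!map$valid)) stop("map must be filled before upsampling")
  ny <- shape[1]; nx <- shape[2]
  # grid sample i covers pixels [i*stride, i*stride + w - 1], so its center
  # sits at i*stride + w/2 - 0.5; Fourier upsampling natively places it at
  # i * (n/m) = i*stride, hence the spatial offset below
  off <- c(map$window[1] / 2 - 0.5, map$window[2] / 2 - 0.5)
  list(x = fourier_upsample(map$tx, ny, nx, off),
       y = fourier_upsample(map$ty, ny, nx, off))
}

#' Multi-level local (elastic) registration
#'
#' Refines an already globally aligned subject against the reference: a
#' 2 x 2 quadrisection first measures a residual affine map A(x, y); then,
#' per window level (4, 8, ... tiles per axis, halving the window until it
#' would fall below `min_window` pixels), per-tile translations are
#' measured, gated, gap-filled, Fourier-upsampled, and accumulated into a
#' local map L(x, y); the subject is rewarped through M = A + L after each
#' pass, iterating up to `max_iter` times per level or until the mean local
#' shift over measured tiles drops below `tol_nm` in real space.
#'
#' @param ref,sub Matrices (e.g. maximum-intensity projections); `sub` must
#'   already be globally aligned.
#' @param pixel_size_nm Isotropic lateral pixel size in nm (default 78).
#' @param min_window Minimum tile window in pixels (default 60).
#' @param max_iter Iterations per level (default 5).
#' @param c Variance-gate constant (default 0.1).
#' @param peak_threshold Phase-correlation peak floor (default 0.02).
#' @param tol_nm Convergence tolerance on the mean local shift (default 1).
#' @return A list of class `local_fit`: `map` (dense pull map, a
#'   `dense_map`), `displacement` (list `x`, `y`: the total displacement
#'   field M - I in pixels, affine part included), `mask` (logical matrix:
#'   Fourier-upsampled coverage of the finest level's measured tiles),
#'   `levels` (per-level `local_shift_map`s), `affine` (the 2 x 2
#'   quadrisection `affine_params7`), and `warped` (the corrected subject).
#' @export
refine_local <- function(ref, sub, pixel_size_nm = 78, min_window = 60,
                         max_iter = 5, c = 0.1, peak_threshold = 0.02,
                         tol_nm = 1) {
  if (!identical(dim(ref), dim(sub))) stop("images must have the same shape")
  ny <- nrow(ref); nx <- ncol(ref)
  tol_px <- tol_nm / pixel_size_nm
  # level 0: 2x2 quadrisection -> residual affine
  qv <- measure_quadrant_vectors(ref, sub)
  dec <- decompose_quadrants(qv, c(ny, nx))
  p0 <- affine_params(t_x = dec$t[1], t_y = dec$t[2],
                      m_x = dec$m[1], m_y = dec$m[2], r_z = dec$r_z)
  amap <- build_affine_map(c(ny, nx), p0)
  lx <- matrix(0, ny, nx)
  ly <- matrix(0, ny, nx)
  warped <- remap_image(sub, amap)
  levels <- list()
  n_tiles <- 4L
  mask_grid <- NULL
  support <- function() {
    my <- amap$map_y + ly; mx <- amap$map_x + lx
    (mx >= 1 & mx <= nx - 2 & my >= 1 & my <= ny - 2) * 1
  }
  while (min(floor(ny / n_tiles), floor(nx / n_tiles)) >= min_window) {
    prev_shift <- Inf
    for (it in seq_len(max_iter)) {
      msk <- support()
      grid <- measure_tile_shifts(ref * msk, warped * msk, n_tiles, c,
                                  peak_threshold)
      grid$level <- length(levels) + 1L
      mean_shift <- mean(sqrt(grid$tx[grid$valid]^2 + grid$ty[grid$valid]^2))
      # iterate only while converging strongly: once the residual stops
      # shrinking by a good factor it is dominated by the per-tile
      # measurement floor, and applying it would only random-walk the map
      if (mean_shift >= 0.25 * prev_shift) break
      prev_shift <- mean_shift
      filled <- fill_empty(grid)
      dense <- upsample_map(filled, c(ny, nx))
      lx <- lx + dense$x
      ly <- ly + dense$y
      warped <- remap_image(sub, list(map_y = amap$map_y + ly,
                                      map_x = amap$map_x + lx))
      levels[[length(levels) + 1L]] <- filled
      if (is.null(mask_grid)) mask_grid <- filled
      if (mean_shift < tol_px) break
    }
    n_tiles <- n_tiles * 2L
  }
  if (length(levels) == 0) stop("image too small for the minimum window")
  mvals <- fourier_upsample(mask_grid$measured * 1, ny, nx,
                            mask_grid$window / 2 - 0.5)
  gx <- matrix(seq_len(nx) - 1, ny, nx, byrow = TRUE)
  gy <- matrix(seq_len(ny) - 1, ny, nx)
  structure(list(map = structure(list(map_y = amap$map_y + ly,
                                      map_x = amap$map_x + lx),
                                 class = "dense_map"),
                 displacement = list(x = amap$map_x + lx - gx,
                                     y = amap$map_y + ly - gy),
                 mask = mvals >= 0.5,
                 levels = levels,
                 affine = p0,
                 warped = warped),
            class = "local_fit")
}

#' @export
print.local_fit <- function(x, ...) {
  nl <- length(x$levels)
  cat(sprintf("Local elastic fit: %d measurement pass%s, final grid %d x %d\n",
              nl, if (nl == 1) "" else "es",
              nrow(x$levels[[nl]]$tx), ncol(x$levels[[nl]]$tx)))
  cat(sprintf("  residual affine: t = (%.3f, %.3f) px, m = (%.5f, %.5f), r_z = %.4f deg\n",
              x$affine$t_x, x$affine$t_y, x$affine$m_x, x$affine$m_y,
              x$affine$r_z))
  cat(sprintf("  max |local shift|: %.3f px; coverage: %.0f%%\n",
              max(abs(c(x$displacement$x, x$displacement$y))),
              100 * mean(x$mask)))
  invisible(x)
}
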