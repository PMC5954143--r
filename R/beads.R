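# Registration-accuracy estimation from bead images: 3D elliptical
# Gaussian fitting, proximity filtering, and channel deviation statistics.

#' Localize beads by 3D elliptical Gaussian fitting
#'
#' Detects local maxima above an intensity threshold (default: background
#' median plus 5 robust standard deviations) and refines each candidate by
#' least-squares fitting of an axis-aligned 3D elliptical Gaussian
#' (amplitude, background, center, and three standard deviations) on a
#' small crop around the peak.  Non-converged fits are dropped.
#'
#' @param vol A `(nz, ny, nx)` array.
#' @param threshold Detection threshold; `NULL` uses
#'   `median(vol) + 5 * mad(vol)`.
#' @param sigma_guess `c(z, y, x)` starting widths in pixels.
#' @param box_half `c(z, y, x)` half-size of the fitting crop; default
#'   `ceiling(3 * sigma_guess)`.
#' @return A data frame with one row per bead: `z`, `y`, `x` (0-based
#'   pixel coordinates), `amplitude`, `background`, `sigma_z`, `sigma_y`,
#'   `sigma_x`.  Empty when nothing is detected.
#' @export
fit_beads_3d <- function(vol, threshold = NULL,
                         sigma_guess = c(1.2, 1.8, 1.8),
                         box_half = NULL) {
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (is.null(threshold))
    threshold <- stats::median(vol) + 5 * stats::mad(vol)
  if (is.null(box_half)) box_half <- ceiling(3 * sigma_guess)
  empty <- data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                      amplitude = numeric(0), background = numeric(0),
                      sigma_z = numeric(0), sigma_y = numeric(0),
                      sigma_x = numeric(0))
  cand <- which(vol > threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) return(empty)
  # keep strict local maxima over the 26-neighborhood
  is_max <- vapply(seq_len(nrow(cand)), function(k) {
    z <- cand[k, 1]; y <- cand[k, 2]; x <- cand[k, 3]
    nb <- vol[max(1, z - 1):min(nz, z + 1),
              max(1, y - 1):min(ny, y + 1),
              max(1, x - 1):min(nx, x + 1)]
    vol[z, y, x] >= max(nb)
  }, logical(1))
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  # suppress duplicate maxima closer than one PSF width
  ord <- order(vol[cand], decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!keep[k]) next
    if (k < nrow(cand)) {
      later <- (k + 1):nrow(cand)
      dd <- sqrt(((cand[later, 1] - cand[k, 1]) / (2 * sigma_guess[1]))^2 +
                   ((cand[later, 2] - cand[k, 2]) / (2 * sigma_guess[2]))^2 +
                   ((cand[later, 3] - cand[k, 3]) / (2 * sigma_guess[3]))^2)
      keep[later[dd < 1]] <- FALSE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(cand))) {
    z0 <- cand[k, 1]; y0 <- cand[k, 2]; x0 <- cand[k, 3]
    zr <- max(1, z0 - box_half[1]):min(nz, z0 + box_half[1])
    yr <- max(1, y0 - box_half[2]):min(ny, y0 + box_half[2])
    xr <- max(1, x0 - box_half[3]):min(nx, x0 + box_half[3])
    crop <- vol[zr, yr, xr, drop = FALSE]
    df <- expand.grid(z = zr - 1, y = yr - 1, x = xr - 1)
    df$v <- as.vector(crop)
    start <- list(A = unname(vol[z0, y0, x0] - min(crop)), b = min(crop),
                  cz = unname(z0 - 1), cy = unname(y0 - 1),
                  cx = unname(x0 - 1),
                  sz = sigma_guess[1], sy = sigma_guess[2],
                  sx = sigma_guess[3])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ A * exp(-((z - cz)^2 / (2 * sz^2) + (y - cy)^2 / (2 * sy^2) +
                        (x - cx)^2 / (2 * sx^2))) + b,
        data = df, start = start,
        lower = c(A = 0, b = -Inf, cz = min(df$z), cy = min(df$y),
                  cx = min(df$x), sz = 0.3, sy = 0.3, sx = 0.3),
        upper = c(A = Inf, b = Inf, cz = max(df$z), cy = max(df$y),
                  cx = max(df$x), sz = 10, sy = 10, sx = 10),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (!all(c("A", "b", "cz", "cy", "cx", "sz", "sy", "sx") %in% names(cf)))
      next
    rows[[length(rows) + 1L]] <-
      data.frame(z = cf[["cz"]], y = cf[["cy"]], x = cf[["cx"]],
                 amplitude = cf[["A"]], background = cf[["b"]],
                 sigma_z = cf[["sz"]], sigma_y = cf[["sy"]],
                 sigma_x = cf[["sx"]])
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Remove beads closer than a minimum separation
#'
#' Drops every bead having any neighbor within `min_separation` (both
#' members of a close pair are removed), emulating the rule of discarding
#' beads closer than twice the diffraction limit.
#'
#' @param table A bead table with columns `z`, `y`, `x` (pixels).
#' @param min_separation_nm Minimum allowed separation (default 500 nm,
#'   i.e. twice a 250 nm lateral diffraction limit).
#' @param pixel_size_nm `c(x, y, z)` pixel size in nm.
#' @return The filtered table.
#' @export
filter_proximity <- function(table, min_separation_nm = 500,
                             pixel_size_nm = c(78, 78, 125)) {
  if (min_separation_nm <= 0) stop("min_separation_nm must be positive")
  n <- nrow(table)
  if (n < 2) return(table)
  if (length(pixel_size_nm) == 1) pixel_size_nm <- rep(pixel_size_nm, 3)
  pos <- cbind(table$x * pixel_size_nm[1],
               table$y * pixel_size_nm[2],
               table$z * pixel_size_nm[3])
  dd <- as.matrix(stats::dist(pos))
  diag(dd) <- Inf
  table[apply(dd, 1, min) >= min_separation_nm, , drop = FALSE]
}

#' Channel-to-channel bead deviations
#'
#' Pairs beads across channels by mutual nearest neighbor against the
#' reference channel and reports per-bead deviations and their summary.
#'
#' @param tables A list of bead tables (one per channel), each with
#'   columns `z`, `y`, `x` in pixels.
#' @param reference Index of the reference channel (default 1).
#' @param pixel_size_nm `c(x, y, z)` nm.
#' @param max_match_nm Maximum pairing distance (default 500 nm).
#' @return A list with `pairs` (data frame: channel, reference bead row,
#'   dz/dy/dx in nm, `d_xy`, `d_xyz` in nm) and `summary` (per channel:
#'   mean and SD of the XY and XYZ distances, and pair count).
#' @export
channel_deviation <- function(tables, reference = 1,
                              pixel_size_nm = c(78, 78, 125),
                              max_match_nm = 500) {
  if (length(pixel_size_nm) == 1) pixel_size_nm <- rep(pixel_size_nm, 3)
  ref <- tables[[reference]]
  if (nrow(ref) == 0) stop("empty reference bead table")
  scale_pos <- function(t) cbind(t$x * pixel_size_nm[1],
                                 t$y * pixel_size_nm[2],
                                 t$z * pixel_size_nm[3])
  rp <- scale_pos(ref)
  pairs <- list()
  for (ch in setdiff(seq_along(tables), reference)) {
    tb <- tables[[ch]]
    if (nrow(tb) == 0) next
    sp <- scale_pos(tb)
    # mutual nearest neighbors within the matching radius
    dmat <- outer(rowSums(rp^2), rep(1, nrow(sp))) +
      outer(rep(1, nrow(rp)), rowSums(sp^2)) - 2 * rp %*% t(sp)
    dmat[dmat < 0] <- 0
    dmat <- sqrt(dmat)
    nn_ref <- apply(dmat, 1, which.min)
    nn_sub <- apply(dmat, 2, which.min)
    for (i in seq_len(nrow(rp))) {
      j <- nn_ref[i]
      if (nn_sub[j] == i && dmat[i, j] <= max_match_nm) {
        dv <- sp[j, ] - rp[i, ]
        pairs[[length(pairs) + 1L]] <-
          data.frame(channel = ch, ref_bead = i,
                     dx = dv[1], dy = dv[2], dz = dv[3],
                     d_xy = sqrt(dv[1]^2 + dv[2]^2),
                     d_xyz = sqrt(sum(dv^2)))
      }
    }
  }
  if (length(pairs) == 0) stop("no matched bead pairs between channels")
  pairs <- do.call(rbind, pairs)
  summ <- do.call(rbind, lapply(split(pairs, pairs$channel), function(g)
    data.frame(channel = g$channel[1], n = nrow(g),
               mean_xy = mean(g$d_xy), sd_xy = stats::sd(g$d_xy),
               mean_xyz = mean(g$d_xyz), sd_xyz = stats::sd(g$d_xyz))))
  rownames(summ) <- NULL
  list(pairs = pairs, summary = summ)
}
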