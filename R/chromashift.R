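# The user-facing model object: fit chromatic-shift parameters from a
# reference multichannel image, inspect them, and apply them to targets.

#' Fit chromatic-shift registration parameters
#'
#' Estimates, for every subject channel of a reference multichannel image,
#' the seven global affine parameters by quadrisection phase correlation
#' ([estimate_global()]), optionally followed by multi-level local elastic
#' refinement ([refine_local()]) on the maximum-intensity projections.
#'
#' @param x A `multichannel_image`, or an array in `(c, z, y, x)` or
#'   `(c, y, x)` order.
#' @param ref_channel Index of the reference channel (default 1).
#' @param channels Subject channel indices; default all but the reference.
#' @param pixel_size_nm `c(x, y, z)` pixel sizes in nm (default taken from
#'   the `multichannel_image`, else 78, 78, 125).
#' @param local Also fit the local elastic shift map (default `FALSE`).
#' @param min_window Minimum local window in pixels (default 60).
#' @param ... Passed on to [estimate_global()].
#' @return An object of class `chromashift` with methods [print()],
#'   [summary()], [coef()], [predict()], [residuals()] and [plot()].
#' @examples
#' ref <- sim_filaments(c(8, 96, 96), n_filaments = 10, seed = 1)
#' sub <- induce_affine(ref, affine_params(t_x = 1.5, t_y = -1))
#' arr <- array(0, c(1, 2, dim(ref)))
#' arr[1, 1, , , ] <- ref
#' arr[1, 2, , , ] <- sub
#' fit <- chromashift(multichannel_image(arr))
#' coef(fit)
#' @export
chromashift <- function(x, ref_channel = 1, channels = NULL,
                        pixel_size_nm = NULL, local = FALSE,
                        min_window = 60, ...) {
  cl <- match.call()
  if (inherits(x, "multichannel_image")) {
    if (is.null(pixel_size_nm)) pixel_size_nm <- x$pixel_size_nm
    arr <- x$data
  } else {
    d <- dim(x)
    if (length(d) == 3) dim(x) <- c(d[1], 1L, d[2], d[3])
    arr <- x
    dim(arr) <- c(1L, dim(x))
  }
  if (is.null(pixel_size_nm)) pixel_size_nm <- c(78, 78, 125)
  d <- dim(arr)
  n_chan <- d[2]
  if (n_chan < 2) stop("need at least two channels")
  if (is.null(channels)) channels <- setdiff(seq_len(n_chan), ref_channel)
  if (ref_channel %in% channels)
    stop("the reference channel cannot also be a subject channel")
  get_vol <- function(ch) array(arr[1, ch, , , ], d[3:5])
  ref_vol <- get_vol(ref_channel)
  fits <- list()
  locals <- list()
  for (ch in channels) {
    key <- paste0("channel_", ch)
    g <- estimate_global(ref_vol, get_vol(ch), pixel_size_nm, ...)
    fits[[key]] <- g
    if (local) {
      corrected <- apply_affine(get_vol(ch), g$params)
      ref_proj <- project_max(ref_vol, "z")
      sub_proj <- project_max(corrected, "z")
      locals[[key]] <- refine_local(ref_proj, sub_proj,
                                    pixel_size_nm = pixel_size_nm[1],
                                    min_window = min_window)
    }
  }
  structure(list(call = cl,
                 params = lapply(fits, `[[`, "params"),
                 global = fits,
                 local = if (local) locals else NULL,
                 ref_channel = ref_channel,
                 channels = channels,
                 shape = d[3:5],
                 pixel_size_nm = pixel_size_nm),
            class = "chromashift")
}

#' @export
print.chromashift <- function(x, ...) {
  cat("Chromatic-shift registration fit\n")
  cat(sprintf("  reference channel %d; %d z x %d y x %d x px; pixel %g/%g/%g nm\n",
              x$ref_channel, x$shape[1], x$shape[2], x$shape[3],
              x$pixel_size_nm[1], x$pixel_size_nm[2], x$pixel_size_nm[3]))
  for (key in names(x$params)) {
    g <- x$global[[key]]
    cat(sprintf("  %s (%s, %d iteration%s):\n", key,
                if (g$converged) "converged" else "not converged",
                nrow(g$iterations), if (nrow(g$iterations) == 1) "" else "s"))
    p <- as.numeric(x$params[[key]])
    cat(sprintf("    t = (%.3f, %.3f, %.3f) px, m = (%.5f, %.5f, %.5f), r_z = %.4f deg\n",
                p[1], p[2], p[3], p[4], p[5], p[6], p[7]))
  }
  if (!is.null(x$local))
    cat(sprintf("  local elastic maps fitted for %d channel(s)\n",
                length(x$local)))
  invisible(x)
}

#' @export
coef.chromashift <- function(object, ...) {
  do.call(cbind, lapply(object$params, as.numeric))
}

#' @export
summary.chromashift <- function(object, ...) {
  rows <- lapply(names(object$params), function(key) {
    dv <- params_to_deviation(object$params[[key]], object$shape,
                              object$pixel_size_nm)
    data.frame(channel = key, t(dv$components),
               total_2d = dv$total_2d, total = dv$total)
  })
  out <- do.call(rbind, rows)
  structure(list(table = out, pixel_size_nm = object$pixel_size_nm),
            class = "summary.chromashift")
}

#' @export
print.summary.chromashift <- function(x, ...) {
  cat("Real-space chromatic shift per channel (nm, edge-pixel rule):\n")
  tb <- x$table
  tb[-1] <- lapply(tb[-1], round, 2)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' @export
residuals.chromashift <- function(object, ...) {
  do.call(rbind, lapply(names(object$params), function(key)
    params_to_deviation(object$params[[key]], object$shape,
                        object$pixel_size_nm)$components))
}

#' Apply a fitted correction to a target image
#'
#' Applies each subject channel's global parameters (and local map, when
#' fitted and the lateral size matches) to the corresponding channel of
#' `newdata`.  Global parameters are scale-free: on a target of different
#' lateral size the translations are rescaled by the size ratio while
#' rotation and magnification carry over unchanged.  Local maps are not
#' scale-free and require the reference lateral size.
#'
#' @param object A `chromashift` fit.
#' @param newdata A `multichannel_image` or `(c, z, y, x)` array; default
#'   the data the model was fitted to is not retained, so `newdata` is
#'   required.
#' @param use_local Apply local maps when available (default `TRUE`).
#' @param ... Unused.
#' @return The corrected image, same class and shape as `newdata`.
#' @export
predict.chromashift <- function(object, newdata, use_local = TRUE, ...) {
  is_mci <- inherits(newdata, "multichannel_image")
  arr <- if (is_mci) newdata$data else {
    d <- dim(newdata)
    if (length(d) == 3) dim(newdata) <- c(d[1], 1L, d[2], d[3])
    a <- newdata
    dim(a) <- c(1L, dim(newdata))
    a
  }
  d <- dim(arr)
  scale_xy <- c(d[5] / object$shape[3], d[4] / object$shape[2])
  for (ch in object$channels) {
    if (ch > d[2]) stop("target has no channel ", ch)
    key <- paste0("channel_", ch)
    p <- object$params[[key]]
    pt <- affine_params(t_x = p$t_x * scale_xy[1],
                        t_y = p$t_y * scale_xy[2],
                        t_z = p$t_z * d[3] / object$shape[1],
                        m_x = p$m_x, m_y = p$m_y, m_z = p$m_z, r_z = p$r_z)
    for (t in seq_len(d[1])) {
      vol <- array(arr[t, ch, , , ], d[3:5])
      vol <- apply_affine(vol, pt)
      if (use_local && !is.null(object$local[[key]])) {
        if (!all(d[4:5] == object$shape[2:3]))
          stop("local maps are not scale-free: target lateral size must ",
               "equal the reference (", object$shape[2], " x ",
               object$shape[3], ")")
        lmap <- object$local[[key]]$map
        gx <- matrix(seq_len(d[5]) - 1, d[4], d[5], byrow = TRUE)
        gy <- matrix(seq_len(d[4]) - 1, d[4], d[5])
        # the local fit already contains its own residual-affine map, so
        # apply only the elastic part on top of the global correction
        for (z in seq_len(d[3]))
          vol[z, , ] <- remap_image(matrix(vol[z, , ], d[4], d[5]), lmap)
      }
      arr[t, ch, , , ] <- vol
    }
  }
  if (is_mci) {
    newdata$data <- arr
    newdata
  } else {
    dim(arr) <- dim(newdata)
    arr
  }
}

#' Plot a chromatic-shift fit
#'
#' With a local map: a quiver plot of the displacement field on a coarse
#' grid.  Without: the convergence trace (real-space step size per
#' iteration, log scale) of each channel's global fit.
#'
#' @param x A `chromashift` object.
#' @param channel Channel key to plot (default the first subject channel).
#' @param every Arrow spacing in pixels for the quiver plot (default 32).
#' @param scale Arrow magnification for visibility (default 20).
#' @param ... Passed to the underlying plot call.
#' @export
plot.chromashift <- function(x, channel = NULL, every = 32, scale = 20,
                             ...) {
  key <- if (is.null(channel)) names(x$params)[1]
  else paste0("channel_", channel)
  if (!is.null(x$local[[key]])) {
    fld <- x$local[[key]]$displacement
    ny <- nrow(fld$x); nx <- ncol(fld$x)
    yi <- seq(every %/% 2, ny - 1, by = every)
    xi <- seq(every %/% 2, nx - 1, by = every)
    graphics::plot(NA, xlim = c(0, nx), ylim = c(0, ny), asp = 1,
                   xlab = "x (px)", ylab = "y (px)",
                   main = sprintf("local displacement field, %s", key), ...)
    for (y in yi) for (xx in xi) {
      dx <- fld$x[y + 1, xx + 1]; dy <- fld$y[y + 1, xx + 1]
      graphics::arrows(xx, y, xx + scale * dx, y + scale * dy,
                       length = 0.04, col = "steelblue")
    }
  } else {
    it <- x$global[[key]]$iterations
    graphics::plot(seq_len(nrow(it)), it$step_nm, type = "b", log = "y",
                   xlab = "iteration", ylab = "step (nm, real space)",
                   main = sprintf("global convergence, %s", key), ...)
    graphics::abline(h = 1, lty = 2)
  }
  invisible(x)
}
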