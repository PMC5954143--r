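# File I/O: multi-page TIFF stacks with JSON sidecars, and the JSON
# registration-parameter file.

#' Multichannel image container
#'
#' A light container around a 5D intensity array in canonical
#' `(t, c, z, y, x)` order with per-axis pixel sizes in nm.
#'
#' @param data A numeric array; 2D `(y, x)`, 3D `(z, y, x)`, 4D
#'   `(c, z, y, x)` or 5D `(t, c, z, y, x)` (singleton axes are padded on
#'   the left).
#' @param pixel_size_nm `c(x, y, z)` pixel sizes in nm.
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(data, pixel_size_nm = c(78, 78, 125)) {
  d <- dim(data)
  if (is.null(d)) stop("data must be an array")
  if (length(d) > 5) stop("at most 5 axes (t, c, z, y, x) supported")
  dim(data) <- c(rep(1L, 5 - length(d)), d)
  if (length(pixel_size_nm) == 1) pixel_size_nm <- rep(pixel_size_nm, 3)
  structure(list(data = data, pixel_size_nm = pixel_size_nm),
            class = "multichannel_image")
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("multichannel_image: %d t x %d c x %d z x %d y x %d x px",
              d[1], d[2], d[3], d[4], d[5]),
      sprintf("(pixel %g x %g x %g nm)\n", x$pixel_size_nm[1],
              x$pixel_size_nm[2], x$pixel_size_nm[3]))
  invisible(x)
}

axes_to_dims <- function(axes) {
  ax <- strsplit(axes, "")[[1]]
  if (!all(ax %in% c("t", "c", "z", "y", "x")) || anyDuplicated(ax))
    stop("axes must be distinct characters from 't', 'c', 'z', 'y', 'x'")
  if (paste(utils::tail(ax, 2), collapse = "") != "yx")
    stop("axes must end in 'yx' (pages are y-x planes)")
  ax
}

#' Read a multi-page TIFF stack
#'
#' Pages are y-x planes; the leading axes (given slowest-first in `axes`,
#' e.g. `"czyx"` for channel-major z-stacks) enumerate the pages.  A JSON
#' sidecar `<path>.json` written by [write_stack()] restores the intensity
#' scale of float data and the pixel sizes.
#'
#' @param path TIFF file path.
#' @param axes Axis order, a permutation of a subset of `"tczyx"` ending in
#'   `"yx"`.
#' @param shape Sizes of the leading (non-yx) axes, in the order given by
#'   `axes`; optional when there is at most one leading axis.
#' @param pixel_size_nm `c(x, y, z)` nm; overridden by the sidecar.
#' @return A `multichannel_image`.
#' @export
read_stack <- function(path, axes = "zyx", shape = NULL,
                       pixel_size_nm = c(78, 78, 125)) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  dims <- lapply(pages, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    stop("ragged TIFF: page 1 and page ",
         which(vapply(dims, paste, "", collapse = "x") !=
                 paste(dims[[1]], collapse = "x"))[1], " differ in shape")
  ax <- axes_to_dims(axes)
  lead <- ax[seq_len(length(ax) - 2)]
  if (is.null(shape)) shape <- if (length(lead) == 0) integer(0)
  else length(pages)
  if (prod(shape) != length(pages))
    stop(sprintf("axis spec implies %d pages but the file has %d",
                 prod(shape), length(pages)))
  # pages arrive in the unit range; the sidecar restores the original
  # intensity scale (2^bits - 1 for integer data, the recorded maximum for
  # float data), so integer stacks round-trip bit-exactly
  scale <- 1
  round_int <- FALSE
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$bits) && meta$bits < 32) {
      scale <- 2^meta$bits - 1
      round_int <- TRUE
    } else if (!is.null(meta$scale)) scale <- meta$scale
    if (!is.null(meta$pixel_size_nm)) pixel_size_nm <- meta$pixel_size_nm
  }
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  sizes <- stats::setNames(rep(1L, 5), c("t", "c", "z", "y", "x"))
  sizes[lead] <- shape
  sizes["y"] <- ny; sizes["x"] <- nx
  arr <- array(0, unname(sizes))
  idx <- rep(1L, length(lead))
  for (p in seq_along(pages)) {
    pos <- stats::setNames(rep(1L, 3), c("t", "c", "z"))
    pos[lead] <- idx
    pg <- pages[[p]] * scale
    if (round_int) pg <- round(pg)
    arr[pos["t"], pos["c"], pos["z"], , ] <- pg
    # advance the page counter, fastest axis last
    for (a in rev(seq_along(lead))) {
      idx[a] <- idx[a] + 1L
      if (idx[a] <= shape[a]) break
      idx[a] <- 1L
    }
  }
  multichannel_image(arr, pixel_size_nm)
}

#' Write a multi-page TIFF stack
#'
#' Integer data are stored at the requested bit depth (bit-exact round
#' trip); float data are rescaled to the unit range and the scale recorded
#' in a JSON sidecar `<path>.json` together with the pixel sizes.
#'
#' @param x A `multichannel_image` or numeric array.
#' @param path Output TIFF path.
#' @param bits 8, 16 (integer) or 32 (float).
#' @param pixel_size_nm Recorded in the sidecar when `x` is a plain array.
#' @return Invisibly, `path`.
#' @export
write_stack <- function(x, path, bits = 32, pixel_size_nm = c(78, 78, 125)) {
  if (!inherits(x, "multichannel_image"))
    x <- multichannel_image(x, pixel_size_nm)
  d <- dim(x$data)
  pages <- list()
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) for (z in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- matrix(x$data[t, c, z, , ], d[4], d[5])
  if (bits %in% c(8L, 16L)) {
    top <- 2^bits - 1
    pages <- lapply(pages, function(p) {
      p[p < 0] <- 0; p[p > top] <- top
      round(p) / top
    })
    scale <- top
  } else {
    mx <- max(abs(unlist(lapply(pages, max))), 1e-12)
    lo <- min(unlist(lapply(pages, min)))
    if (lo < 0) stop("negative intensities cannot be stored; offset first")
    scale <- mx
    pages <- lapply(pages, function(p) p / scale)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, reduce = FALSE)
  jsonlite::write_json(list(scale = scale, bits = bits,
                            pixel_size_nm = x$pixel_size_nm,
                            shape = d),
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write registration parameters to JSON
#'
#' One entry per subject channel with the seven parameters, the reference
#' shape and pixel sizes; numbers are written at full precision, so a
#' read/write round trip is exact to well below 1e-9.
#'
#' @param params A named list of `affine_params7` (names are channel
#'   labels), or a single `affine_params7`.
#' @param path Output path.
#' @param shape Reference image shape `c(nz, ny, nx)`.
#' @param pixel_size_nm `c(x, y, z)` nm.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params, path, shape = NULL,
                         pixel_size_nm = c(78, 78, 125)) {
  if (inherits(params, "affine_params7")) params <- list(channel_2 = params)
  doc <- list(
    software = paste0("chromashift ",
                      as.character(utils::packageVersion("chromashift"))),
    reference_shape = shape,
    pixel_size_nm = pixel_size_nm,
    channels = lapply(params, function(p) unclass(p)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read registration parameters from JSON
#'
#' @param path A file written by [write_params()].
#' @return A list with `channels` (named list of `affine_params7`),
#'   `reference_shape`, and `pixel_size_nm`.
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  channels <- lapply(doc$channels, function(p) do.call(affine_params, p))
  list(channels = channels,
       reference_shape = doc$reference_shape,
       pixel_size_nm = doc$pixel_size_nm)
}
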