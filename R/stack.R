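#' Multi-channel image stack
#'
#' An `image_stack` holds a 3D voxel grid (one or more channels) together
#' with its physical voxel sizes and channel names. Voxel data are stored
#' internally in `(z, c, y, x)` order; every function in the package
#' consumes this order only. The physical coordinate of voxel
#' `(k, j, i)` (1-based) is `((k - 0.5) * dz, (j - 0.5) * dy, (i - 0.5) * dx)`
#' micrometres, i.e. coordinates refer to voxel centers.
#'
#' @param voxels a 3D array `(z, y, x)` for a single channel, or a 4D array
#'   `(z, c, y, x)` for several channels. Values must be finite and
#'   non-negative.
#' @param voxel_size_um numeric length-3 `(dz, dy, dx)` in micrometres,
#'   all positive.
#' @param channels character vector of channel names (defaults to
#'   `"ch1"`, `"ch2"`, ...).
#' @param dtype_bits source bit depth bookkeeping (default 32).
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size_um, channels = NULL, dtype_bits = 32L) {
  if (length(dim(voxels)) == 3L) {
    dim(voxels) <- c(dim(voxels)[1], 1L, dim(voxels)[2], dim(voxels)[3])
  }
  if (length(dim(voxels)) != 4L) {
    abort("`voxels` must be a 3D (z, y, x) or 4D (z, c, y, x) array")
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0)) {
    abort("`voxel_size_um` must be three positive numbers (dz, dy, dx)")
  }
  nc <- dim(voxels)[2]
  if (is.null(channels)) channels <- paste0("ch", seq_len(nc))
  if (length(channels) != nc) {
    abort(sprintf("channel count (%d) does not match data axis (%d)",
                  length(channels), nc))
  }
  structure(
    list(voxels = voxels, voxel_size_um = voxel_size_um,
         channels = as.character(channels), dtype_bits = as.integer(dtype_bits)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d z-planes x %d x %d px, %d channel(s): %s\n",
              d[1], d[3], d[4], d[2], paste(x$channels, collapse = ", ")))
  cat(sprintf("  voxel size (dz, dy, dx): %s um\n",
              paste(signif(x$voxel_size_um, 4), collapse = " x ")))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Extract a single channel as a 3D array
#'
#' @param stack an `image_stack`.
#' @param channel channel name or index.
#' @return a 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    i <- match(channel, stack$channels)
    if (is.na(i)) abort(sprintf("channel '%s' not present (have: %s)",
                                channel, paste(stack$channels, collapse = ", ")))
  } else i <- as.integer(channel)
  a <- stack$voxels[, i, , , drop = FALSE]
  dim(a) <- dim(stack$voxels)[c(1, 3, 4)]
  a
}

#' Write an image stack to a multi-page 32-bit float TIFF
#'
#' Pages are written z-major, channel-minor (all channels of plane 1, then
#' plane 2, ...). Intensities are stored as 32-bit floats scaled into
#' `[0, 1]`; the scale factor and the physical metadata (voxel size, channel
#' names, plane count) live in a JSON sidecar at `<path>.json` so that a
#' round trip through [read_stack()] restores the stack to float32
#' precision.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  scale <- max(stack$voxels, 1e-12)
  pages <- vector("list", d[1] * d[2])
  p <- 1L
  for (k in seq_len(d[1])) {
    for (ci in seq_len(d[2])) {
      pages[[p]] <- matrix(stack$voxels[k, ci, , ] / scale, d[3], d[4])
      p <- p + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "deflate",
                  reduce = FALSE)
  meta <- list(axes = "zcyx", nz = d[1], channels = stack$channels,
               voxel_size_um = stack$voxel_size_um,
               intensity_scale = scale,
               dtype_bits = stack$dtype_bits)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an image stack from TIFF
#'
#' Reads a single- or multi-page TIFF. Metadata (plane count, channel names,
#' voxel size) is taken from the `<path>.json` sidecar written by
#' [write_stack()] when present; otherwise the file is interpreted as a
#' single-channel z-stack and `voxel_size_um` must be supplied. An explicit
#' `voxel_size_um` always overrides the sidecar.
#'
#' @param path TIFF path.
#' @param voxel_size_um optional `(dz, dy, dx)` override in micrometres.
#' @param channels optional channel-name override.
#' @return an `image_stack`.
#' @export
read_stack <- function(path, voxel_size_um = NULL, channels = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(m) {
    if (length(dim(m)) == 3L) m[, , 1] else m  # collapse RGB pages to grey
  })
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else NULL
  if (is.null(voxel_size_um)) voxel_size_um <- meta$voxel_size_um
  if (is.null(voxel_size_um)) {
    abort("voxel size missing: no metadata sidecar and no `voxel_size_um` override")
  }
  ch <- channels %||% meta$channels %||% "ch1"
  nc <- length(ch)
  npage <- length(pages)
  if (npage %% nc != 0) abort("page count is not a multiple of the channel count")
  nz <- npage %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  scale <- meta$intensity_scale %||% 1
  a <- array(0, c(nz, nc, ny, nx))
  p <- 1L
  for (k in seq_len(nz)) {
    for (ci in seq_len(nc)) {
      a[k, ci, , ] <- pages[[p]] * scale
      p <- p + 1L
    }
  }
  image_stack(a, voxel_size_um, channels = ch,
              dtype_bits = meta$dtype_bits %||% 32L)
}

#' Project a stack along z
#'
#' Per-pixel maximum or arithmetic-mean intensity projection over a range of
#' z-planes, the standard figure-style reductions of confocal stacks.
#'
#' @param stack an `image_stack` or 3D array.
#' @param mode `"max"` or `"mean"`.
#' @param z_range optional integer `(lo, hi)` plane range (1-based, inclusive).
#' @param channel channel to project (required if the stack has several).
#' @return a 2D numeric matrix `(y, x)`.
#' @export
project <- function(stack, mode = c("max", "mean"), z_range = NULL,
                    channel = NULL) {
  mode <- match.arg(mode)
  a <- if (inherits(stack, "image_stack")) {
    if (is.null(channel)) {
      if (length(stack$channels) > 1L) {
        abort("multi-channel stack: supply `channel`")
      }
      channel <- 1L
    }
    get_channel(stack, channel)
  } else stack
  nz <- dim(a)[1]
  if (is.null(z_range)) z_range <- c(1L, nz)
  z_range <- as.integer(z_range)
  if (z_range[1] < 1L || z_range[2] > nz || z_range[1] > z_range[2]) {
    abort("empty or out-of-bounds z_range")
  }
  sub <- a[z_range[1]:z_range[2], , , drop = FALSE]
  if (mode == "max") apply(sub, c(2, 3), max) else colMeans(sub, dims = 1)
}

#' Export a 2D image (or RGB array) as PNG
#'
#' Grey images are linearly rescaled to `range` (default: observed range);
#' RGB arrays are written as-is and must lie in `[0, 1]`.
#'
#' @param image 2D matrix or `(y, x, 3)` array.
#' @param path output PNG path.
#' @param range display range `(lo, hi)` for grey images.
#' @return `path`, invisibly.
#' @export
export_png <- function(image, path, range = NULL) {
  if (length(dim(image)) == 2L) {
    if (is.null(range)) range <- range(image, finite = TRUE)
    if (diff(range) <= 0) range <- range + c(0, 1)
    image <- pmin(pmax((image - range[1]) / diff(range), 0), 1)
    image[!is.finite(image)] <- 0
  }
  png::writePNG(image, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
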