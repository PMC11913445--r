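#' Segmentation parameters
#'
#' Parameters of the 3D object reconstruction: optional in-plane Gaussian
#' blur (sigma in pixels, as applied slice-wise by common viewers), a
#' background estimation mode, an intensity threshold (applied strictly,
#' `intensity > threshold`, after background subtraction), the connectivity
#' of the 3D component labeling, a volume filter excluding plasma-membrane
#' sheets and debris, and an optional automated exclusion of objects whose
#' centroid lies near the cell-mask boundary (a deterministic surrogate for
#' manual erasing of membrane signal).
#'
#' @param blur_sigma_px in-plane Gaussian blur sigma in pixels (0 = off).
#' @param background_mode `"blank_regions"`, `"percentile"` or `"none"`.
#' @param threshold positive intensity threshold; typical immunostaining
#'   stacks in this workflow use values around 600-1200.
#' @param connectivity 6, 18 or 26 (default 26, the usual 3D object-counting
#'   convention).
#' @param volume_filter_um3 `(min, max)`; objects with volume in `(min, max]`
#'   are retained (default `c(0, 5000)`).
#' @param boundary_exclusion_um drop objects whose centroid lies within this
#'   distance of the cell-mask boundary (0 = off).
#' @param percentile background percentile when
#'   `background_mode = "percentile"`.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(blur_sigma_px = 1, background_mode = c("blank_regions", "percentile", "none"),
                                threshold = 1000, connectivity = 26,
                                volume_filter_um3 = c(0, 5000),
                                boundary_exclusion_um = 0, percentile = 0.25) {
  background_mode <- match.arg(background_mode)
  if (threshold <= 0) abort("`threshold` must be positive")
  if (!connectivity %in% c(6, 18, 26)) abort("`connectivity` must be 6, 18 or 26")
  if (length(volume_filter_um3) != 2L ||
      volume_filter_um3[1] >= volume_filter_um3[2]) {
    abort("`volume_filter_um3` must be (min, max) with min < max")
  }
  if (blur_sigma_px < 0 || boundary_exclusion_um < 0) {
    abort("blur sigma and boundary exclusion must be non-negative")
  }
  structure(list(blur_sigma_px = blur_sigma_px, background_mode = background_mode,
                 threshold = threshold, connectivity = as.integer(connectivity),
                 volume_filter_um3 = as.numeric(volume_filter_um3),
                 boundary_exclusion_um = boundary_exclusion_um,
                 percentile = percentile),
            class = "segmentation_params")
}

#' Estimate background from cellular blank regions
#'
#' Returns the mean of the per-region mean intensities over one or more
#' rectangular regions placed outside the cell (the four-blank-region
#' convention of ratiometric imaging). Regions span all z-planes of a 3D
#' input.
#'
#' @param image 2D matrix `(y, x)` or 3D array `(z, y, x)`.
#' @param regions list of integer vectors `c(y0, y1, x0, x1)` (1-based,
#'   inclusive).
#' @return scalar background estimate.
#' @export
estimate_background <- function(image, regions) {
  if (length(regions) == 0L) abort("at least one blank region is required")
  d <- dim(image)
  if (length(d) == 2L) { image <- array(image, c(1L, d)); d <- dim(image) }
  means <- vapply(regions, function(r) {
    r <- as.integer(r)
    if (length(r) != 4L || r[1] < 1L || r[3] < 1L || r[2] > d[2] || r[4] > d[3] ||
        r[1] > r[2] || r[3] > r[4]) {
      abort("blank region (y0, y1, x0, x1) out of bounds")
    }
    mean(image[, r[1]:r[2], r[3]:r[4]])
  }, numeric(1))
  mean(means)
}

#' Subtract a background value, clamping at zero
#'
#' @param image numeric array.
#' @param background scalar background.
#' @return array of the same shape, `pmax(image - background, 0)`.
#' @export
subtract_background <- function(image, background) {
  out <- pmax(image - background, 0)
  dim(out) <- dim(image)
  out
}

#' Threshold a stack
#'
#' Strict thresholding: a voxel is foreground iff `intensity > threshold`,
#' applied uniformly in 3D (background subtraction is assumed done).
#'
#' @param image 3D numeric array `(z, y, x)`.
#' @param threshold positive scalar.
#' @return logical array of the same shape.
#' @export
threshold_stack <- function(image, threshold) {
  if (threshold <= 0) abort("`threshold` must be positive")
  mask <- image > threshold
  dim(mask) <- dim(image)
  mask
}

#' Label 3D connected components
#'
#' Maximal connected foreground sets under the chosen voxel neighborhood
#' share one positive label; labels are contiguous from 1 and assigned in
#' raster-scan order of each component's first-encountered voxel.
#'
#' @param mask logical 3D array `(z, y, x)`.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full neighborhood).
#' @return integer array of labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (length(d) != 3L) abort("`mask` must be a 3D array")
  cpp_label3d(as.logical(mask), as.integer(d), as.integer(connectivity))
}

#' Measure labeled objects
#'
#' Per-object voxel count, volume, integrated and mean intensity, unweighted
#' geometric centroid of member voxel centers (in micrometres), and
#' equivalent-sphere diameter.
#'
#' @param labels integer 3D array from [label_components()].
#' @param intensity numeric 3D array, congruent with `labels`.
#' @param voxel_size_um `(dz, dy, dx)` in micrometres.
#' @return a tibble with one row per object, ordered by label.
#' @export
measure_objects <- function(labels, intensity, voxel_size_um) {
  d <- dim(labels)
  if (!identical(d, dim(intensity))) abort("label and intensity grids differ in shape")
  vs <- as.numeric(voxel_size_um)
  idx <- which(labels > 0L)
  empty <- tibble::tibble(label = integer(), voxel_count = integer(),
                          volume_um3 = numeric(), integrated_intensity = numeric(),
                          mean_intensity = numeric(), centroid_z_um = numeric(),
                          centroid_y_um = numeric(), centroid_x_um = numeric(),
                          equivalent_diameter_um = numeric())
  if (length(idx) == 0L) return(empty)
  lab <- labels[idx]
  zi <- (idx - 1L) %% d[1] + 1L
  yi <- ((idx - 1L) %/% d[1]) %% d[2] + 1L
  xi <- (idx - 1L) %/% (d[1] * d[2]) + 1L
  f <- factor(lab)
  cnt <- as.integer(tabulate(f))
  s_int <- as.numeric(rowsum(intensity[idx], f))
  cz <- as.numeric(rowsum(zi - 0.5, f)) / cnt * vs[1]
  cy <- as.numeric(rowsum(yi - 0.5, f)) / cnt * vs[2]
  cx <- as.numeric(rowsum(xi - 0.5, f)) / cnt * vs[3]
  vol <- cnt * prod(vs)
  tibble::tibble(label = as.integer(levels(f)), voxel_count = cnt,
                 volume_um3 = vol, integrated_intensity = s_int,
                 mean_intensity = s_int / cnt,
                 centroid_z_um = cz, centroid_y_um = cy, centroid_x_um = cx,
                 equivalent_diameter_um = equivalent_diameter(vol))
}

# Minimum distance (um, in-plane) from points to the cell-mask boundary.
mask_boundary_distance <- function(y_um, x_um, cell_mask, voxel_size_um) {
  m <- cell_mask
  d <- dim(m)
  pad <- function(sh_y, sh_x) {
    out <- matrix(FALSE, d[1], d[2])
    ys <- max(1, 1 + sh_y):min(d[1], d[1] + sh_y)
    xs <- max(1, 1 + sh_x):min(d[2], d[2] + sh_x)
    out[ys, xs] <- m[ys - sh_y, xs - sh_x]
    out
  }
  interior <- m & pad(1, 0) & pad(-1, 0) & pad(0, 1) & pad(0, -1)
  boundary <- which(m & !interior, arr.ind = TRUE)
  if (nrow(boundary) == 0L) return(rep(Inf, length(y_um)))
  by <- (boundary[, 1] - 0.5) * voxel_size_um[2]
  bx <- (boundary[, 2] - 0.5) * voxel_size_um[3]
  vapply(seq_along(y_um), function(i) {
    sqrt(min((by - y_um[i])^2 + (bx - x_um[i])^2))
  }, numeric(1))
}

#' Filter measured objects by volume (and optionally by boundary proximity)
#'
#' Keeps objects with `volume_um3` in `(min, max]`. When
#' `boundary_exclusion_um > 0` and a [find_cell_geometry()] result is given,
#' objects whose centroid lies within that in-plane distance of the
#' cell-mask boundary are additionally dropped (automated stand-in for
#' manual erasing of plasma-membrane signal).
#'
#' @param table an object tibble from [measure_objects()].
#' @param params a [segmentation_params()] (supplies the volume filter and
#'   boundary exclusion) or a numeric `(min, max)`.
#' @param cell_geometry optional [find_cell_geometry()] result.
#' @return the filtered tibble.
#' @export
filter_objects <- function(table, params = segmentation_params(),
                           cell_geometry = NULL) {
  if (is.numeric(params)) {
    vf <- params; be <- 0
  } else {
    vf <- params$volume_filter_um3; be <- params$boundary_exclusion_um
  }
  out <- dplyr::filter(table, .data$volume_um3 > vf[1], .data$volume_um3 <= vf[2])
  if (be > 0) {
    if (is.null(cell_geometry)) {
      abort("boundary exclusion requires `cell_geometry`")
    }
    bd <- mask_boundary_distance(out$centroid_y_um, out$centroid_x_um,
                                 cell_geometry$cell_mask,
                                 cell_geometry$voxel_size_um)
    out <- out[bd > be, , drop = FALSE]
  }
  out
}

# Otsu threshold on a numeric matrix/array (256-bin histogram, one value
# for the whole input).
otsu_threshold <- function(x) {
  r <- range(x, finite = TRUE)
  if (diff(r) <= 0) return(r[1])
  flat <- matrix((as.vector(x) - r[1]) / diff(r), ncol = 1)
  EBImage::otsu(EBImage::Image(flat), range = c(0, 1)) * diff(r) + r[1]
}

#' Locate the cell: center plane, mask and 3D geometric center
#'
#' The center plane is the midpoint of the first and last z-planes carrying
#' above-threshold signal (the usual middle-height convention). The cell
#' mask is the hole-filled largest bright region of that plane (Otsu
#' threshold on the plane); the 3D cell center takes its x/y from the mask
#' centroid and its z from the center-plane height.
#'
#' @param image 3D numeric array `(z, y, x)` of the reference channel.
#' @param voxel_size_um `(dz, dy, dx)`.
#' @param threshold intensity threshold marking "signal"; default: Otsu over
#'   the whole stack.
#' @return a list of class `cell_geometry`: `center_plane_z` (index),
#'   `cell_mask` (2D logical), `center_um` (z, y, x), `voxel_size_um`.
#' @export
find_cell_geometry <- function(image, voxel_size_um, threshold = NULL) {
  d <- dim(image)
  vs <- as.numeric(voxel_size_um)
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  has_signal <- vapply(seq_len(d[1]), function(k) any(image[k, , ] > threshold),
                       logical(1))
  if (!any(has_signal)) abort("no above-threshold signal in the stack")
  z0 <- which(has_signal)[1]; z1 <- rev(which(has_signal))[1]
  zc <- as.integer(round((z0 + z1) / 2))
  plane <- image[zc, , ]
  pt <- otsu_threshold(plane)
  bw <- plane > pt
  lab <- label_components(array(bw, c(1L, d[2], d[3])), 6)[1, , ]
  if (max(lab) == 0L) {
    # sparse center plane (no cytosolic haze): fall back to the max
    # projection so some cell footprint exists
    plane <- apply(image, c(2, 3), max)
    pt <- otsu_threshold(plane)
    bw <- plane > pt
    lab <- label_components(array(bw, c(1L, d[2], d[3])), 6)[1, , ]
    if (max(lab) == 0L) abort("no bright region at the center plane")
  }
  keep <- which.max(tabulate(lab))
  m <- lab == keep
  m <- EBImage::fillHull(EBImage::Image(m)) > 0
  m <- matrix(as.logical(m), d[2], d[3])
  w <- which(m, arr.ind = TRUE)
  center <- c((zc - 0.5) * vs[1],
              mean(w[, 1] - 0.5) * vs[2],
              mean(w[, 2] - 0.5) * vs[3])
  structure(list(center_plane_z = zc, cell_mask = m, center_um = center,
                 voxel_size_um = vs, threshold = threshold),
            class = "cell_geometry")
}

#' Segment one channel end to end
#'
#' The full 3D object reconstruction for a channel: optional in-plane blur,
#' background estimation and subtraction (clamped at zero), strict
#' thresholding, 3D connected-component labeling, measurement, and volume
#' filtering.
#'
#' @param stack an [image_stack()] or 3D array.
#' @param params a [segmentation_params()].
#' @param channel channel to segment when `stack` is multi-channel.
#' @param voxel_size_um required when `stack` is a bare array.
#' @param blank_regions list of `c(y0, y1, x0, x1)` rectangles for
#'   `background_mode = "blank_regions"`; defaults to the four image corners
#'   (16 x 16 px), which lie outside a centered cell.
#' @param cell_geometry optional [find_cell_geometry()] result for boundary
#'   exclusion.
#' @return a list of class `elysa_segmentation`: `table` (measured, filtered
#'   tibble), `labels` (integer array), `background`, `params`,
#'   `voxel_size_um`.
#' @export
segment_objects <- function(stack, params = segmentation_params(),
                            channel = NULL, voxel_size_um = NULL,
                            blank_regions = NULL, cell_geometry = NULL) {
  if (inherits(stack, "image_stack")) {
    voxel_size_um <- stack$voxel_size_um
    img <- get_channel(stack, channel %||%
                         if (length(stack$channels) == 1L) 1L else
                           abort("multi-channel stack: supply `channel`"))
  } else {
    if (is.null(voxel_size_um)) abort("`voxel_size_um` required for bare arrays")
    img <- stack
  }
  d <- dim(img)
  if (params$blur_sigma_px > 0) {
    img <- cpp_blur3d(img, d, 0, params$blur_sigma_px, params$blur_sigma_px)
  }
  bg <- switch(params$background_mode,
    none = 0,
    percentile = stats::quantile(img, params$percentile, names = FALSE),
    blank_regions = {
      if (is.null(blank_regions)) {
        s <- 16L
        blank_regions <- list(c(1L, s, 1L, s), c(1L, s, d[3] - s + 1L, d[3]),
                              c(d[2] - s + 1L, d[2], 1L, s),
                              c(d[2] - s + 1L, d[2], d[3] - s + 1L, d[3]))
      }
      estimate_background(img, blank_regions)
    })
  img <- subtract_background(img, bg)
  mask <- threshold_stack(img, params$threshold)
  labels <- label_components(mask, params$connectivity)
  table <- measure_objects(labels, img, voxel_size_um)
  table <- filter_objects(table, params, cell_geometry)
  structure(list(table = table, labels = labels, background = bg,
                 params = params, voxel_size_um = as.numeric(voxel_size_um)),
            class = "elysa_segmentation")
}

#' @export
print.elysa_segmentation <- function(x, ...) {
  cat(sprintf("<elysa_segmentation> %d object(s), background %.1f, threshold %.0f (conn %d)\n",
              nrow(x$table), x$background, x$params$threshold,
              x$params$connectivity))
  invisible(x)
}

#' @export
tidy.elysa_segmentation <- function(x, ...) x$table
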