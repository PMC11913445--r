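#' Background-corrected ratio image of two acidity channels
#'
#' Mean-projects each channel along z, estimates each channel's background
#' as the mean of the given cellular blank regions, subtracts it (clamped at
#' zero), and divides A by B. Pixels whose corrected denominator does not
#' exceed `floor` are masked invalid rather than producing unstable ratios;
#' the default floor is three times the standard deviation of the
#' denominator's blank-region pixels.
#'
#' @param stack_a,stack_b numerator / denominator channels: 3D arrays,
#'   single-channel [image_stack()]s, or 2D matrices (already projected).
#' @param blank_regions list of `c(y0, y1, x0, x1)` rectangles outside the
#'   cell (the customary four).
#' @param floor positive denominator floor, or `NULL` for the default.
#' @return a list of class `ratio_image`: `values` (2D, `NA` where invalid),
#'   `valid_mask`, `background_a`, `background_b`, `floor`, and a
#'   `warning` string when no pixel is valid.
#' @export
make_ratio_image <- function(stack_a, stack_b, blank_regions, floor = NULL) {
  proj <- function(s) {
    if (inherits(s, "image_stack")) s <- get_channel(s, 1L)
    if (length(dim(s)) == 3L) colMeans(s, dims = 1) else s
  }
  a <- proj(stack_a); b <- proj(stack_b)
  if (!identical(dim(a), dim(b))) abort("channel A and B grids are not congruent")
  bg_a <- estimate_background(a, blank_regions)
  bg_b <- estimate_background(b, blank_regions)
  if (is.null(floor)) {
    px <- unlist(lapply(blank_regions, function(r) b[r[1]:r[2], r[3]:r[4]]))
    floor <- 3 * stats::sd(px)
    if (!is.finite(floor) || floor <= 0) floor <- .Machine$double.eps
  }
  if (floor <= 0) abort("`floor` must be positive")
  a_c <- pmax(a - bg_a, 0)
  b_c <- pmax(b - bg_b, 0)
  valid <- b_c > floor
  values <- matrix(NA_real_, nrow(a), ncol(a))
  values[valid] <- a_c[valid] / b_c[valid]
  res <- structure(list(values = values, valid_mask = valid,
                        background_a = bg_a, background_b = bg_b,
                        floor = floor, warning = NULL),
                   class = "ratio_image")
  if (!any(valid)) {
    res$warning <- "no valid pixels: denominator never exceeded the floor"
    warn(res$warning)
  }
  res
}

#' @export
print.ratio_image <- function(x, ...) {
  cat(sprintf("<ratio_image> %d x %d px, %.1f%% valid, backgrounds A %.2f / B %.2f, floor %.3g\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$valid_mask),
              x$background_a, x$background_b, x$floor))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Per-object ratio statistics
#'
#' Median and mean ratio over each labeled region's valid pixels; objects
#' with no valid pixel are flagged and carry no number.
#'
#' @param ratio a [make_ratio_image()] result.
#' @param labels_2d integer 2D label image from a projection-plane
#'   segmentation, congruent with the ratio image.
#' @return tibble with `label`, `n_pixels`, `n_valid`, `median_ratio`,
#'   `mean_ratio`, `flagged` (`TRUE` when no valid pixel).
#' @export
per_object_ratio <- function(ratio, labels_2d) {
  if (!identical(dim(ratio$values), dim(labels_2d))) {
    abort("label image is not congruent with the ratio image")
  }
  labs <- sort(unique(labels_2d[labels_2d > 0L]))
  rows <- lapply(labs, function(l) {
    sel <- labels_2d == l
    vals <- ratio$values[sel & ratio$valid_mask]
    tibble::tibble(label = as.integer(l), n_pixels = sum(sel),
                   n_valid = length(vals),
                   median_ratio = if (length(vals)) stats::median(vals) else NA_real_,
                   mean_ratio = if (length(vals)) mean(vals) else NA_real_,
                   flagged = length(vals) == 0L)
  })
  dplyr::bind_rows(rows)
}

#' Intensity profile along a line
#'
#' Samples the image by bilinear interpolation at `n_samples` evenly spaced
#' points from `p0` to `p1`; distances are measured from `p0` (the origin,
#' 0 um). Pixel centers follow the half-pixel convention used throughout.
#'
#' @param image 2D numeric matrix `(y, x)`.
#' @param p0_um,p1_um `(y, x)` endpoints in micrometres; must lie inside the
#'   image.
#' @param n_samples number of sample points (>= 2).
#' @param pixel_size_um `(dy, dx)` in micrometres.
#' @return tibble with `distance_um` and `intensity`.
#' @export
line_profile <- function(image, p0_um, p1_um, n_samples = 100,
                         pixel_size_um = c(1, 1)) {
  d <- dim(image)
  ps <- as.numeric(pixel_size_um)
  extent <- d * ps
  for (p in list(p0_um, p1_um)) {
    if (any(p < 0) || any(p > extent)) abort("profile endpoint outside the image")
  }
  t <- seq(0, 1, length.out = n_samples)
  y <- p0_um[1] + t * (p1_um[1] - p0_um[1])
  x <- p0_um[2] + t * (p1_um[2] - p0_um[2])
  # continuous pixel coordinates: center of pixel (j, i) is at (j-0.5, i-0.5) px
  fy <- pmin(pmax(y / ps[1] - 0.5, 0), d[1] - 1)
  fx <- pmin(pmax(x / ps[2] - 0.5, 0), d[2] - 1)
  j0 <- pmin(floor(fy), d[1] - 2); i0 <- pmin(floor(fx), d[2] - 2)
  wy <- fy - j0; wx <- fx - i0
  v00 <- image[cbind(j0 + 1, i0 + 1)]; v01 <- image[cbind(j0 + 1, i0 + 2)]
  v10 <- image[cbind(j0 + 2, i0 + 1)]; v11 <- image[cbind(j0 + 2, i0 + 2)]
  val <- v00 * (1 - wy) * (1 - wx) + v01 * (1 - wy) * wx +
         v10 * wy * (1 - wx) + v11 * wy * wx
  dist <- t * sqrt(sum((p1_um - p0_um)^2))
  tibble::tibble(distance_um = dist, intensity = val)
}

# "Fire"-style lookup table: 32 fixed control points linearly interpolated.
fire_lut <- function(n = 256L) {
  r <- c(0, 0, 1, 25, 49, 73, 98, 122, 146, 162, 173, 184, 195, 207, 217, 229,
         240, 252, 255, 255, 255, 255, 255, 255, 255, 255, 255, 255, 255, 255,
         255, 255)
  g <- c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 14, 35, 57, 79, 101, 117, 133,
         147, 161, 175, 190, 205, 219, 234, 248, 255, 255, 255, 255)
  b <- c(0, 61, 96, 130, 165, 192, 220, 227, 210, 181, 151, 122, 93, 64, 35, 5,
         0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 35, 98, 160, 223, 255)
  xs <- seq(0, 1, length.out = length(r))
  xo <- seq(0, 1, length.out = n)
  cbind(stats::approx(xs, r, xo)$y, stats::approx(xs, g, xo)$y,
        stats::approx(xs, b, xo)$y) / 255
}

#' Render a ratio image through a fire lookup table
#'
#' Deterministically maps ratio values through a fixed 256-entry fire-style
#' color table over the given display range (values at or below the range
#' minimum take the first color, at or above the maximum the last); invalid
#' pixels are rendered black.
#'
#' @param ratio a [make_ratio_image()] result.
#' @param range display range `(lo, hi)`, `lo < hi`.
#' @param path optional PNG output path.
#' @return `(y, x, 3)` RGB array in `[0, 1]`, invisibly if written.
#' @export
export_fire_lut <- function(ratio, range, path = NULL) {
  if (length(range) != 2L || range[1] >= range[2]) {
    abort("`range` must be (lo, hi) with lo < hi")
  }
  lut <- fire_lut(256L)
  v <- ratio$values
  idx <- 1L + as.integer(round(pmin(pmax((v - range[1]) / diff(range), 0), 1) * 255))
  d <- dim(v)
  rgb <- array(0, c(d, 3L))
  ok <- which(ratio$valid_mask)
  for (ch in 1:3) {
    plane <- matrix(0, d[1], d[2])
    plane[ok] <- lut[idx[ok], ch]
    rgb[, , ch] <- plane
  }
  if (!is.null(path)) {
    png::writePNG(rgb, path)
    return(invisible(rgb))
  }
  rgb
}
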