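#' @importFrom ggplot2 ggplot aes geom_col geom_errorbar geom_point geom_text
#'   geom_raster geom_line labs scale_fill_gradientn coord_fixed theme_minimal
NULL

#' Plot a size distribution
#'
#' Object counts per equivalent-diameter bin.
#'
#' @param object a [bin_by_diameter()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.binned_distribution <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mid <- (df$bin_lo + df$bin_hi) / 2
  df$width <- df$bin_hi - df$bin_lo
  ggplot(df, aes(x = .data$mid, y = .data$count, width = .data$width * 0.9)) +
    geom_col(fill = "grey30") +
    labs(x = "equivalent diameter (µm)", y = "object count") +
    theme_minimal()
}

#' Plot a group comparison
#'
#' Group means with SEM error bars and compact-letter annotations; groups
#' sharing a letter are not significantly different.
#'
#' @param object a [compare_groups()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.group_comparison <- function(object, ...) {
  df <- object$groups
  df$group <- factor(df$group, levels = df$group)
  ypad <- max(df$mean + ifelse(is.na(df$sem), 0, df$sem)) * 0.06
  ggplot(df, aes(x = .data$group, y = .data$mean)) +
    geom_col(fill = "grey60") +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.2) +
    geom_text(aes(y = .data$mean + ifelse(is.na(.data$sem), 0, .data$sem) + ypad,
                  label = .data$letter)) +
    labs(x = NULL, y = "mean ± SEM") +
    theme_minimal()
}

#' Plot a ratio image
#'
#' Renders the ratio image with a fire-style gradient; invalid pixels are
#' blank.
#'
#' @param object a [make_ratio_image()] result.
#' @param range optional display range `(lo, hi)`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ratio_image <- function(object, range = NULL, ...) {
  v <- object$values
  df <- expand.grid(y = seq_len(nrow(v)), x = seq_len(ncol(v)))
  df$ratio <- as.vector(v)
  if (is.null(range)) range <- range(v, na.rm = TRUE)
  lut <- fire_lut(64)
  cols <- grDevices::rgb(lut[, 1], lut[, 2], lut[, 3])
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$ratio)) +
    geom_raster() +
    scale_fill_gradientn(colours = cols, limits = range, na.value = "black") +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "ratio") +
    theme_minimal()
}

#' Plot a line profile
#'
#' @param profile a [line_profile()] tibble (or several bound together with
#'   a `channel` column).
#' @return a ggplot.
#' @export
plot_line_profile <- function(profile) {
  p <- ggplot(profile, aes(x = .data$distance_um, y = .data$intensity))
  if ("channel" %in% names(profile)) {
    p <- p + geom_line(aes(colour = .data$channel))
  } else {
    p <- p + geom_line()
  }
  p + labs(x = "distance (µm)", y = "intensity") + theme_minimal()
}
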