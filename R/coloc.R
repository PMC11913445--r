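#' Segment a partner channel
#'
#' Identical machinery to the reference-channel segmentation, with the
#' partner channel's own threshold; provided as a named step so pipelines
#' read naturally.
#'
#' @inheritParams segment_objects
#' @return an `elysa_segmentation`.
#' @export
segment_partner <- function(stack, params = segmentation_params(),
                            channel = NULL, voxel_size_um = NULL,
                            blank_regions = NULL, cell_geometry = NULL) {
  segment_objects(stack, params, channel = channel,
                  voxel_size_um = voxel_size_um, blank_regions = blank_regions,
                  cell_geometry = cell_geometry)
}

# Physical coordinate -> 1-based voxel index by floor division; a coordinate
# exactly on a voxel edge maps to the higher-index voxel.
coord_to_index <- function(coord_um, voxel_size, n) {
  i <- floor(coord_um / voxel_size) + 1L
  as.integer(pmin(pmax(i, 1L), n))
}

#' Object-based colocalization: partner centers inside reference objects
#'
#' A partner object is colocalized iff the voxel containing its geometric
#' center carries a nonzero reference label; a reference object is
#' double-positive iff at least one partner center maps to it.
#'
#' @param partner_table measured partner-object tibble (centroids in um).
#' @param reference_labels integer reference label array `(z, y, x)`.
#' @param voxel_size_um `(dz, dy, dx)`.
#' @return a list of class `coloc_result`: `partner` (tibble with
#'   `host_label`, 0 = none, and `colocalized`), `reference` (tibble with
#'   `label`, `n_partner_centers`, `double_positive`).
#' @export
centers_in_objects <- function(partner_table, reference_labels, voxel_size_um) {
  d <- dim(reference_labels)
  vs <- as.numeric(voxel_size_um)
  host <- integer(nrow(partner_table))
  if (nrow(partner_table) > 0L) {
    zi <- coord_to_index(partner_table$centroid_z_um, vs[1], d[1])
    yi <- coord_to_index(partner_table$centroid_y_um, vs[2], d[2])
    xi <- coord_to_index(partner_table$centroid_x_um, vs[3], d[3])
    host <- reference_labels[cbind(zi, yi, xi)]
  }
  partner <- dplyr::mutate(partner_table, host_label = as.integer(host),
                           colocalized = host > 0L)
  ref_labels <- sort(unique(reference_labels[reference_labels > 0L]))
  hits <- table(factor(host[host > 0L], levels = ref_labels))
  reference <- tibble::tibble(label = as.integer(ref_labels),
                              n_partner_centers = as.integer(hits),
                              double_positive = as.integer(hits) > 0L)
  structure(list(partner = partner, reference = reference),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %d/%d partner object(s) colocalized; %d/%d reference object(s) double-positive\n",
              sum(x$partner$colocalized), nrow(x$partner),
              sum(x$reference$double_positive), nrow(x$reference)))
  invisible(x)
}

#' Summarize double-positive reference objects
#'
#' Count, total volume, mean and SEM of the equivalent diameter of
#' double-positive reference objects, plus the per-zone double-positive
#' fraction when the reference table carries zones. With no double
#' positives the means are flagged `NA`.
#'
#' @param coloc a [centers_in_objects()] result.
#' @param reference_table the measured reference tibble the labels came
#'   from (optionally with a `zone` column).
#' @return one-row tibble of summaries, with a `by_zone` tibble attached as
#'   attribute `"by_zone"` when zones are present.
#' @export
double_positive_summary <- function(coloc, reference_table) {
  tb <- dplyr::left_join(reference_table,
                         coloc$reference[, c("label", "double_positive")],
                         by = "label")
  tb$double_positive[is.na(tb$double_positive)] <- FALSE
  dp <- dplyr::filter(tb, .data$double_positive)
  n <- nrow(dp)
  out <- tibble::tibble(
    n_double_positive = n,
    fraction_double_positive = if (nrow(tb)) n / nrow(tb) else NA_real_,
    total_volume_um3 = sum(dp$volume_um3),
    mean_diameter_um = if (n > 0) mean(dp$equivalent_diameter_um) else NA_real_,
    sem_diameter_um = if (n > 1) stats::sd(dp$equivalent_diameter_um) / sqrt(n)
                      else NA_real_)
  if ("zone" %in% names(tb)) {
    by_zone <- tb |>
      dplyr::group_by(.data$zone, .drop = FALSE) |>
      dplyr::summarise(n = dplyr::n(),
                       n_double_positive = sum(.data$double_positive),
                       fraction = ifelse(dplyr::n() > 0,
                                         sum(.data$double_positive) / dplyr::n(),
                                         NA_real_),
                       .groups = "drop")
    attr(out, "by_zone") <- by_zone
  }
  out
}
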