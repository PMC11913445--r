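#' Zone parameters
#'
#' Radial zoning cutoffs on the distal distance: objects farther than
#' `peripheral_min_um` from the cell center are peripheral, closer than
#' `medial_max_um` are medial (both strict); the band in between is
#' reported as intermediate rather than discarded.
#'
#' @param peripheral_min_um peripheral cutoff (default 30).
#' @param medial_max_um medial cutoff (default 25).
#' @return a `zone_params` list.
#' @export
zone_params <- function(peripheral_min_um = 30, medial_max_um = 25) {
  if (medial_max_um >= peripheral_min_um) {
    abort("`medial_max_um` must be smaller than `peripheral_min_um`")
  }
  structure(list(peripheral_min_um = peripheral_min_um,
                 medial_max_um = medial_max_um), class = "zone_params")
}

#' Mean centroid-to-surface distance per object
#'
#' Surface voxels are member voxels with at least one face-adjacent
#' (6-neighborhood) non-member voxel; the statistic is the mean Euclidean
#' distance, in physical micrometres, from the object's centroid to the
#' surface-voxel centers. A single-voxel object has distance 0. This is the
#' term that corrects the radial distance of large objects for their own
#' extent.
#'
#' @param table measured object tibble (must carry centroids and `label`).
#' @param labels integer label array the table was measured from.
#' @param voxel_size_um `(dz, dy, dx)`.
#' @return the tibble with a `mean_surface_distance_um` column.
#' @export
add_surface_distance <- function(table, labels, voxel_size_um) {
  d <- dim(labels)
  vs <- as.numeric(voxel_size_um)
  # face-exposed member voxels: any 6-neighbor with a different label
  shift_differs <- function(axis, by) {
    out <- array(TRUE, d)  # out-of-volume neighbors count as exposure
    if (d[axis] == 1L) return(out)
    if (axis == 1L) {
      src <- if (by > 0) 1:(d[1] - 1) else 2:d[1]
      dst <- if (by > 0) 2:d[1] else 1:(d[1] - 1)
      out[dst, , ] <- labels[dst, , ] != labels[src, , ]
    } else if (axis == 2L) {
      src <- if (by > 0) 1:(d[2] - 1) else 2:d[2]
      dst <- if (by > 0) 2:d[2] else 1:(d[2] - 1)
      out[, dst, ] <- labels[, dst, ] != labels[, src, ]
    } else {
      src <- if (by > 0) 1:(d[3] - 1) else 2:d[3]
      dst <- if (by > 0) 2:d[3] else 1:(d[3] - 1)
      out[, , dst] <- labels[, , dst] != labels[, , src]
    }
    out
  }
  exposed <- labels > 0L &
    (shift_differs(1L, 1L) | shift_differs(1L, -1L) |
     shift_differs(2L, 1L) | shift_differs(2L, -1L) |
     shift_differs(3L, 1L) | shift_differs(3L, -1L))
  idx <- which(exposed)
  lab <- labels[idx]
  zc <- ((idx - 1L) %% d[1] + 0.5) * vs[1]
  yc <- (((idx - 1L) %/% d[1]) %% d[2] + 0.5) * vs[2]
  xc <- ((idx - 1L) %/% (d[1] * d[2]) + 0.5) * vs[3]
  msd <- vapply(seq_len(nrow(table)), function(i) {
    sel <- lab == table$label[i]
    if (!any(sel)) return(NA_real_)
    mean(sqrt((zc[sel] - table$centroid_z_um[i])^2 +
              (yc[sel] - table$centroid_y_um[i])^2 +
              (xc[sel] - table$centroid_x_um[i])^2))
  }, numeric(1))
  dplyr::mutate(table, mean_surface_distance_um = msd)
}

#' Distal distance of each object from the cell center
#'
#' `distal = ||centroid - cell_center|| + mean_surface_distance`: the
#' centroid distance plus the object's mean centroid-to-surface distance,
#' so that a large assembly touching the cortex is not scored as medial
#' merely because its centroid sits inward.
#'
#' @param table object tibble with centroids and `mean_surface_distance_um`.
#' @param cell_center_um `(z, y, x)` cell center in micrometres, or a
#'   [find_cell_geometry()] result.
#' @return the tibble with `centroid_distance_um` and `distal_distance_um`.
#' @export
distal_distance <- function(table, cell_center_um) {
  if (inherits(cell_center_um, "cell_geometry")) {
    cell_center_um <- cell_center_um$center_um
  }
  cd <- sqrt((table$centroid_z_um - cell_center_um[1])^2 +
             (table$centroid_y_um - cell_center_um[2])^2 +
             (table$centroid_x_um - cell_center_um[3])^2)
  dplyr::mutate(table, centroid_distance_um = cd,
                distal_distance_um = cd + .data$mean_surface_distance_um)
}

#' Classify distal distances into radial zones
#'
#' Strict at both cutoffs: `> peripheral_min` is peripheral, `< medial_max`
#' is medial, anything else (including values exactly at a cutoff) is
#' intermediate.
#'
#' @param distal_distance_um numeric vector of distal distances.
#' @param zones a [zone_params()].
#' @return factor with levels `peripheral`, `medial`, `intermediate`.
#' @export
classify_zone <- function(distal_distance_um, zones = zone_params()) {
  out <- rep("intermediate", length(distal_distance_um))
  out[distal_distance_um > zones$peripheral_min_um] <- "peripheral"
  out[distal_distance_um < zones$medial_max_um] <- "medial"
  factor(out, levels = c("peripheral", "medial", "intermediate"))
}

#' Add a zone column to an object table
#'
#' @param table tibble with `distal_distance_um`.
#' @param zones a [zone_params()].
#' @return the tibble with a `zone` factor column.
#' @export
add_zones <- function(table, zones = zone_params()) {
  dplyr::mutate(table, zone = classify_zone(.data$distal_distance_um, zones))
}

#' Zone counts of large objects
#'
#' Counts of peripheral / medial / intermediate objects restricted to
#' equivalent diameters strictly above `d_min_um` (the large-assembly
#' comparisons use 4 um).
#'
#' @param table tibble with `equivalent_diameter_um` and `distal_distance_um`
#'   (or `zone`).
#' @param d_min_um diameter cutoff (strict).
#' @param zones a [zone_params()].
#' @return one-row tibble `n_peripheral`, `n_medial`, `n_intermediate`.
#' @export
zone_counts <- function(table, d_min_um = 4, zones = zone_params()) {
  big <- dplyr::filter(table, .data$equivalent_diameter_um > d_min_um)
  z <- if ("zone" %in% names(big)) big$zone else
    classify_zone(big$distal_distance_um, zones)
  tb <- table(factor(z, levels = c("peripheral", "medial", "intermediate")))
  tibble::tibble(n_peripheral = as.integer(tb[["peripheral"]]),
                 n_medial = as.integer(tb[["medial"]]),
                 n_intermediate = as.integer(tb[["intermediate"]]))
}
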