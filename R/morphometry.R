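#' Equivalent-sphere diameter
#'
#' Diameter of the sphere with the object's measured volume,
#' `d = (6 V / pi)^(1/3)`. Strictly increasing in volume.
#'
#' @param volume_um3 positive volume(s) in cubic micrometres.
#' @return diameter(s) in micrometres.
#' @export
equivalent_diameter <- function(volume_um3) {
  if (any(!is.finite(volume_um3)) || any(volume_um3 <= 0)) {
    abort("volumes must be positive and finite")
  }
  (6 * volume_um3 / pi)^(1 / 3)
}

#' Canonical diameter bin edges
#'
#' One fine partition (0.2, 0.4, 0.6, 0.8, 1, 2, ..., 10 um) unifying the
#' overlapping verbal size classes used in stage comparisons (0.2-0.8,
#' 1-3, 3-7, 9-10 um, ...); coarse classes are sums of fine bins.
#'
#' @return numeric vector of increasing bin edges.
#' @export
default_bin_edges <- function() c(0.2, 0.4, 0.6, 0.8, 1:10)

#' Bin objects by equivalent diameter
#'
#' Bins are half-open `[lo, hi)` except the last, which is closed
#' `[lo, hi]`, so boundary diameters are assigned deterministically.
#' Objects outside the edge range are never silently dropped: their counts
#' are carried in the `n_below`/`n_above` attributes (and shown by `print`).
#'
#' @param table object tibble with `equivalent_diameter_um` and
#'   (optionally) `volume_um3`.
#' @param edges strictly increasing bin edges in micrometres.
#' @return a tibble of class `binned_distribution` with columns `bin_lo`,
#'   `bin_hi`, `count`, `volume_um3`.
#' @export
bin_by_diameter <- function(table, edges = default_bin_edges()) {
  if (any(diff(edges) <= 0)) abort("`edges` must be strictly increasing")
  d <- table$equivalent_diameter_um
  v <- if ("volume_um3" %in% names(table)) table$volume_um3 else rep(0, length(d))
  nb <- length(edges) - 1L
  bin <- findInterval(d, edges, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= nb
  counts <- tabulate(bin[inside], nbins = nb)
  vols <- as.numeric(tapply(v[inside], factor(bin[inside], levels = seq_len(nb)),
                            sum))
  vols[is.na(vols)] <- 0
  out <- tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                        count = as.integer(counts), volume_um3 = vols)
  structure(out, class = c("binned_distribution", class(out)),
            edges = edges,
            n_below = sum(d < edges[1]), n_above = sum(d > edges[length(edges)]))
}

#' @export
print.binned_distribution <- function(x, ...) {
  NextMethod()
  cat(sprintf("# out of range: %d below, %d above\n",
              attr(x, "n_below"), attr(x, "n_above")))
  invisible(x)
}

#' Per-bin ratio of two size distributions
#'
#' The per-bin ratio of counts (e.g. an MII/GV maturation ratio). A 0/0 bin
#' is flagged undefined (`NA` ratio, `undefined = TRUE`); a positive count
#' over zero is `Inf` and not flagged.
#'
#' @param dist_num,dist_den [bin_by_diameter()] results on identical edges.
#' @return tibble with `bin_lo`, `bin_hi`, `ratio`, `undefined`.
#' @export
stage_ratio <- function(dist_num, dist_den) {
  if (!isTRUE(all.equal(attr(dist_num, "edges"), attr(dist_den, "edges")))) {
    abort("distributions were binned on different edges")
  }
  num <- dist_num$count; den <- dist_den$count
  ratio <- num / den
  undef <- den == 0 & num == 0
  ratio[undef] <- NA_real_
  tibble::tibble(bin_lo = dist_num$bin_lo, bin_hi = dist_num$bin_hi,
                 ratio = ratio, undefined = undef)
}

#' Fraction of total object volume above a diameter cutoff
#'
#' @param table nonempty object tibble.
#' @param d_min_um diameter cutoff in micrometres (strict `>`).
#' @return fraction in `[0, 1]`.
#' @export
volume_fraction_above <- function(table, d_min_um) {
  if (nrow(table) == 0L) abort("empty object table")
  sum(table$volume_um3[table$equivalent_diameter_um > d_min_um]) /
    sum(table$volume_um3)
}

#' Per-object intensity density
#'
#' Adds `intensity_per_volume = integrated_intensity / volume_um3`, the
#' signal-density statistic separating bright compact assemblies from
#' dimmer ones of the same size.
#'
#' @param table measured object tibble.
#' @return the tibble with an `intensity_per_volume` column.
#' @export
intensity_per_volume <- function(table) {
  dplyr::mutate(table,
                intensity_per_volume = .data$integrated_intensity / .data$volume_um3)
}

#' Mean intensity density per diameter class
#'
#' @param table measured object tibble.
#' @param edges diameter bin edges.
#' @return tibble with `bin_lo`, `bin_hi`, `n`, `mean_intensity_per_volume`.
#' @export
binned_intensity_per_volume <- function(table, edges = default_bin_edges()) {
  t2 <- intensity_per_volume(table)
  nb <- length(edges) - 1L
  bin <- findInterval(t2$equivalent_diameter_um, edges, rightmost.closed = TRUE)
  inside <- bin >= 1L & bin <= nb
  f <- factor(bin[inside], levels = seq_len(nb))
  n <- as.integer(table(f))
  m <- as.numeric(tapply(t2$intensity_per_volume[inside], f, mean))
  tibble::tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                 n = n, mean_intensity_per_volume = m)
}
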