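# Independent oracles used across the test suite. Deliberately written
# against the definitions, not against the package internals.

offsets_for <- function(connectivity) {
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  m <- abs(g$dz) + abs(g$dy) + abs(g$dx)
  keep <- m > 0 & m <= switch(as.character(connectivity), "6" = 1, "18" = 2, "26" = 3)
  as.matrix(g[keep, ])
}

# Frontier-based flood fill over a logical 3D array; labels components in
# raster order of first foreground voxel.
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  off <- offsets_for(connectivity)
  labels <- array(0L, d)
  lab <- 0L
  for (seed in which(mask)) {
    if (labels[seed] > 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    while (length(frontier)) {
      zi <- (frontier - 1L) %% nz + 1L
      yi <- ((frontier - 1L) %/% nz) %% ny + 1L
      xi <- (frontier - 1L) %/% (nz * ny) + 1L
      cand <- integer(0)
      for (r in seq_len(nrow(off))) {
        zz <- zi + off[r, 1]; yy <- yi + off[r, 2]; xx <- xi + off[r, 3]
        ok <- zz >= 1L & zz <= nz & yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
        if (any(ok)) {
          cand <- c(cand, (xx[ok] - 1L) * nz * ny + (yy[ok] - 1L) * nz + zz[ok])
        }
      }
      cand <- unique(cand)
      cand <- cand[mask[cand] & labels[cand] == 0L]
      labels[cand] <- lab
      frontier <- cand
    }
  }
  labels
}

# Relabel a label volume by order of first occurrence, so partitions can be
# compared independently of label numbering.
canonical_labels <- function(labels) {
  v <- as.vector(labels)
  seen <- unique(v[v > 0L])
  map <- integer(max(c(0L, seen)))
  map[seen] <- seq_along(seen)
  out <- v
  out[v > 0L] <- map[v[v > 0L]]
  array(out, dim(labels))
}

# Brute-force rasterization of a sphere: voxel centers within the radius.
brute_sphere_voxels <- function(center_um, diameter_um, dims, voxel_size_um) {
  cz <- (seq_len(dims[1]) - 0.5) * voxel_size_um[1]
  cy <- (seq_len(dims[2]) - 0.5) * voxel_size_um[2]
  cx <- (seq_len(dims[3]) - 0.5) * voxel_size_um[3]
  d2 <- outer(outer((cz - center_um[1])^2, (cy - center_um[2])^2, `+`),
              (cx - center_um[3])^2, `+`)
  which(d2 <= (diameter_um / 2)^2)
}

# Exhaustive point-in-voxel lookup: find the voxel whose half-open physical
# extent [lo, hi) contains the point, then return its label.
brute_point_label <- function(point_um, labels, voxel_size_um) {
  d <- dim(labels)
  idx <- integer(3)
  for (ax in 1:3) {
    lo <- (seq_len(d[ax]) - 1) * voxel_size_um[ax]
    hi <- seq_len(d[ax]) * voxel_size_um[ax]
    k <- which(point_um[ax] >= lo & point_um[ax] < hi)
    if (length(k) != 1L) return(NA_integer_)
    idx[ax] <- k
  }
  labels[idx[1], idx[2], idx[3]]
}

# Small noiseless multi-object fixture used by several tests.
small_noiseless_scene <- function(seed = 11, diameters = c(3, 4, 5, 6, 3.5)) {
  phantoms <- lapply(seq_along(diameters), function(i) {
    phantom_spec(i, "sphere", diameter_um = diameters[i],
                 radial_distance_um = 4 + 3 * i,
                 channels = c(LAMP1 = 2000))
  })
  scene_spec(grid_shape = c(60L, 96L, 96L), voxel_size_um = c(1, 0.5, 0.5),
             cell_diameter_um = 46, phantoms = phantoms,
             psf_sigma_um = c(0, 0, 0), background_counts = 0,
             cytosol_counts = 0, read_noise_sd = 0, poisson = FALSE,
             clearance_um = 1.5, seed = seed)
}
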