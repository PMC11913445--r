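#' Phantom specification
#'
#' Describes one organellar assembly to place in a synthetic cell. Assemblies
#' are spherical, ellipsoidal, or chains of overlapping spheres (the
#' concatenated morphology seen around cleavage). Position is given either as
#' an absolute center or as a radial distance from the cell center with a
#' direction drawn uniformly on the sphere at render time.
#'
#' @param id unique positive integer identifier.
#' @param shape `"sphere"`, `"ellipsoid"` or `"chain"`.
#' @param diameter_um sphere diameter (shape `"sphere"`).
#' @param semi_axes_um `(az, ay, ax)` semi-axes (shape `"ellipsoid"`).
#' @param chain_diameters_um sphere diameters along the chain (shape `"chain"`).
#' @param chain_overlap fraction in `[0, 0.5)` by which consecutive chain
#'   spheres overlap.
#' @param center_um absolute `(z, y, x)` center in micrometres, or `NULL`.
#' @param radial_distance_um distance of the (chain: centroid) center from the
#'   cell center; used when `center_um` is `NULL`.
#' @param channels named numeric vector of mean photon counts per channel the
#'   phantom emits in (e.g. `c(LAMP1 = 2000, RAB5 = 2000)`).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(id, shape = c("sphere", "ellipsoid", "chain"),
                         diameter_um = NULL, semi_axes_um = NULL,
                         chain_diameters_um = NULL, chain_overlap = 0.25,
                         center_um = NULL, radial_distance_um = NULL,
                         channels = c(LAMP1 = 2000)) {
  shape <- match.arg(shape)
  id <- as.integer(id)
  if (is.na(id) || id < 1L) abort("phantom `id` must be a positive integer")
  if (shape == "sphere") {
    if (is.null(diameter_um) || diameter_um <= 0) {
      abort(sprintf("phantom %d: sphere needs a positive `diameter_um`", id))
    }
  } else if (shape == "ellipsoid") {
    if (is.null(semi_axes_um) || length(semi_axes_um) != 3L ||
        any(semi_axes_um <= 0)) {
      abort(sprintf("phantom %d: ellipsoid needs three positive semi-axes", id))
    }
  } else {
    if (is.null(chain_diameters_um) || length(chain_diameters_um) < 2L ||
        any(chain_diameters_um <= 0)) {
      abort(sprintf("phantom %d: chain needs >=2 positive sphere diameters", id))
    }
    if (chain_overlap < 0 || chain_overlap >= 0.5) {
      abort(sprintf("phantom %d: chain overlap must be in [0, 0.5)", id))
    }
  }
  if (is.null(channels) || is.null(names(channels)) || any(channels < 0)) {
    abort(sprintf("phantom %d: `channels` must be a named non-negative vector", id))
  }
  structure(list(id = id, shape = shape, diameter_um = diameter_um,
                 semi_axes_um = semi_axes_um,
                 chain_diameters_um = chain_diameters_um,
                 chain_overlap = chain_overlap, center_um = center_um,
                 radial_distance_um = radial_distance_um,
                 channels = channels),
            class = "phantom_spec")
}

# Radius of the smallest sphere containing the phantom, for placement checks.
phantom_bounding_radius <- function(ph) {
  switch(ph$shape,
    sphere = ph$diameter_um / 2,
    ellipsoid = max(ph$semi_axes_um),
    chain = {
      d <- ph$chain_diameters_um
      gaps <- (utils::head(d, -1) + utils::tail(d, -1)) / 2 * (1 - ph$chain_overlap)
      span <- sum(gaps) + d[1] / 2 + d[length(d)] / 2
      span / 2
    })
}

# Decompose a placed phantom into spheres for collision/fit checks
# (ellipsoids fall back to their bounding sphere).
phantom_spheres <- function(ph, ctr, dir) {
  switch(ph$shape,
    sphere = list(list(c = ctr, r = ph$diameter_um / 2)),
    ellipsoid = list(list(c = ctr, r = max(ph$semi_axes_um))),
    chain = {
      cc <- chain_centers(ph, dir)
      lapply(seq_len(nrow(cc)), function(i)
        list(c = ctr + cc[i, ], r = ph$chain_diameters_um[i] / 2))
    })
}

# Centers of the chain spheres relative to the chain centroid, along `dir`.
chain_centers <- function(ph, dir) {
  d <- ph$chain_diameters_um
  gaps <- (utils::head(d, -1) + utils::tail(d, -1)) / 2 * (1 - ph$chain_overlap)
  pos <- c(0, cumsum(gaps))
  pos <- pos - mean(pos)
  outer(pos, dir)  # n x 3
}

#' Scene specification
#'
#' Parametric description of a synthetic confocal acquisition: one roughly
#' spherical cell centered in the grid, containing a list of phantoms,
#' imaged through a separable Gaussian PSF with Poisson photon noise,
#' additive Gaussian read noise, and a constant background. Two preset
#' acquisition regimes mirror common practice: 81 z-planes at dz = 1 um
#' (immunostaining) and 41 planes at dz = 2 um (live dye imaging).
#'
#' @param grid_shape integer `(nz, ny, nx)`.
#' @param voxel_size_um `(dz, dy, dx)` in micrometres.
#' @param cell_diameter_um cell diameter (default 75, an oocyte-scale cell).
#' @param phantoms list of [phantom_spec()] objects with unique ids.
#' @param channels character vector of channel names to render; defaults to
#'   the union of phantom channels.
#' @param psf_sigma_um `(sz, sy, sx)` Gaussian PSF sigmas in micrometres.
#' @param background_counts constant background photon count; scalar or named
#'   per-channel vector.
#' @param cytosol_counts mean photon count of diffuse cytosolic signal added
#'   inside the cell volume (scalar or named per-channel vector); emulates
#'   the cytosolic haze of real stainings, which is also what delineates the
#'   cell for geometry finding.
#' @param read_noise_sd standard deviation of additive Gaussian read noise.
#' @param poisson logical; draw Poisson photon noise (default `TRUE`).
#' @param clearance_um minimum surface-to-surface clearance enforced between
#'   phantoms placed by radial distance.
#' @param seed integer RNG seed; a scene spec plus its seed fully determines
#'   the rendered stack bit for bit.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(grid_shape = c(81L, 256L, 256L),
                       voxel_size_um = c(1, 0.35, 0.35),
                       cell_diameter_um = 75, phantoms = list(),
                       channels = NULL, psf_sigma_um = c(1, 0.35, 0.35),
                       background_counts = 100, cytosol_counts = 0,
                       read_noise_sd = 10,
                       poisson = TRUE, clearance_um = 1, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L)) {
    abort("`grid_shape` must be three positive integers (nz, ny, nx)")
  }
  if (any(voxel_size_um <= 0)) abort("voxel sizes must be positive")
  if (any(psf_sigma_um < 0)) abort("PSF sigmas must be non-negative")
  if (any(background_counts < 0) || any(cytosol_counts < 0) || read_noise_sd < 0) {
    abort("background, cytosol and read noise must be non-negative")
  }
  ids <- vapply(phantoms, function(p) p$id, integer(1))
  if (anyDuplicated(ids)) abort("phantom ids must be unique")
  if (is.null(channels)) {
    channels <- unique(unlist(lapply(phantoms, function(p) names(p$channels))))
    if (length(channels) == 0L) channels <- "LAMP1"
  }
  extent <- grid_shape * voxel_size_um
  if (cell_diameter_um > min(extent)) {
    abort(sprintf("cell (%.1f um) does not fit in the grid (min extent %.1f um)",
                  cell_diameter_um, min(extent)))
  }
  structure(list(grid_shape = grid_shape, voxel_size_um = as.numeric(voxel_size_um),
                 cell_diameter_um = cell_diameter_um, phantoms = phantoms,
                 channels = channels, psf_sigma_um = as.numeric(psf_sigma_um),
                 background_counts = background_counts,
                 cytosol_counts = cytosol_counts,
                 read_noise_sd = read_noise_sd, poisson = poisson,
                 clearance_um = clearance_um, seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec> grid %s @ %s um, cell %.0f um, %d phantom(s), channels: %s, seed %d\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$voxel_size_um, 3), collapse = "x"),
              x$cell_diameter_um, length(x$phantoms),
              paste(x$channels, collapse = ", "), x$seed))
  invisible(x)
}

# Physical (z, y, x) center of the grid = cell center.
scene_center_um <- function(spec) spec$grid_shape * spec$voxel_size_um / 2

#' Rasterize a phantom onto the scene grid
#'
#' A voxel belongs to the solid iff its physical center lies inside the
#' analytic shape (chains are unions of spheres). Partial-volume effects
#' enter only later, through PSF blur.
#'
#' @param phantom a [phantom_spec()] with a resolved `center_um`.
#' @param scene a [scene_spec()] (supplies grid geometry).
#' @param direction unit `(z, y, x)` vector for chain orientation.
#' @return integer vector of linear voxel indices (column-major over
#'   `(z, y, x)`).
#' @export
rasterize_phantom <- function(phantom, scene, direction = c(0, 0, 1)) {
  if (is.null(phantom$center_um)) {
    abort(sprintf("phantom %d has no resolved center", phantom$id))
  }
  vs <- scene$voxel_size_um
  dims <- scene$grid_shape
  rb <- phantom_bounding_radius(phantom)
  ctr <- phantom$center_um
  lo <- ctr - rb; hi <- ctr + rb
  if (any(lo < 0) || any(hi > dims * vs)) {
    abort(sprintf("phantom %d extends beyond the image grid", phantom$id))
  }
  spheres <- switch(phantom$shape,
    sphere = list(list(c = ctr, r = phantom$diameter_um / 2)),
    ellipsoid = NULL,
    chain = {
      cc <- chain_centers(phantom, direction)
      lapply(seq_len(nrow(cc)), function(i)
        list(c = ctr + cc[i, ], r = phantom$chain_diameters_um[i] / 2))
    })
  ilo <- pmax(1L, floor(lo / vs - 1) + 1L)
  ihi <- pmin(dims, ceiling(hi / vs + 1))
  kz <- ilo[1]:ihi[1]; ky <- ilo[2]:ihi[2]; kx <- ilo[3]:ihi[3]
  cz <- (kz - 0.5) * vs[1]; cy <- (ky - 0.5) * vs[2]; cx <- (kx - 0.5) * vs[3]
  nz <- length(kz); ny <- length(ky); nx <- length(kx)
  inside <- array(FALSE, c(nz, ny, nx))
  if (phantom$shape == "ellipsoid") {
    a <- phantom$semi_axes_um
    qz <- ((cz - ctr[1]) / a[1])^2
    qy <- ((cy - ctr[2]) / a[2])^2
    qx <- ((cx - ctr[3]) / a[3])^2
    inside <- outer(outer(qz, qy, `+`), qx, `+`) <= 1
  } else {
    for (s in spheres) {
      qz <- (cz - s$c[1])^2; qy <- (cy - s$c[2])^2; qx <- (cx - s$c[3])^2
      inside <- inside | (outer(outer(qz, qy, `+`), qx, `+`) <= s$r^2)
    }
  }
  w <- which(inside, arr.ind = TRUE)
  if (nrow(w) == 0L) {
    # sub-voxel solid capturing no voxel center: digitize to the single
    # voxel containing the solid's center
    i <- pmin(pmax(floor(ctr / vs) + 1L, 1L), dims)
    return(as.integer((i[3] - 1) * dims[1] * dims[2] + (i[2] - 1) * dims[1] + i[1]))
  }
  zi <- kz[w[, 1]]; yi <- ky[w[, 2]]; xi <- kx[w[, 3]]
  as.integer((xi - 1) * dims[1] * dims[2] + (yi - 1) * dims[1] + zi)
}

# Sample a uniform direction on the unit sphere.
runif_direction <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

#' Render a synthetic scene
#'
#' Places phantoms (resolving radial placements with directions drawn
#' uniformly on the sphere, rejected until the phantom fits inside the cell
#' and clears previously placed phantoms), rasterizes them, and simulates the
#' acquisition per channel as
#' `Poisson(blur(intensity field) + background) + N(0, read_noise_sd)`,
#' clamped at zero. Ground truth (label volume and per-phantom table) is
#' computed from the pre-blur rasterization.
#'
#' @param spec a [scene_spec()].
#' @return a list of class `elysa_scene` with elements `stack` (an
#'   [image_stack()]), `truth` (list with `labels`, an integer `(z, y, x)`
#'   array, and `table`, a tibble of true per-phantom measurements), and
#'   `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  dims <- spec$grid_shape
  vs <- spec$voxel_size_um
  n <- prod(dims)
  cc <- scene_center_um(spec)
  cell_r <- spec$cell_diameter_um / 2

  placed <- list()   # flat list of spheres (center, radius) of placed phantoms
  labels <- integer(n)
  fields <- lapply(spec$channels, function(ch) numeric(n))
  names(fields) <- spec$channels
  rows <- list()

  # place big assemblies first: small phantoms barely constrain them, while
  # the reverse order can make a large phantom unplaceable at its radius
  place_order <- order(-vapply(spec$phantoms, phantom_bounding_radius, numeric(1)))
  fits_cell <- function(spheres) {
    all(vapply(spheres, function(s)
      sqrt(sum((s$c - cc)^2)) + s$r <= cell_r, logical(1)))
  }
  clears <- function(spheres) {
    for (s in spheres) {
      for (p in placed) {
        if (sqrt(sum((s$c - p$c)^2)) < s$r + p$r + spec$clearance_um) {
          return(FALSE)
        }
      }
    }
    TRUE
  }
  for (ph in spec$phantoms[place_order]) {
    dir <- c(0, 0, 1)
    if (is.null(ph$center_um)) {
      if (is.null(ph$radial_distance_um)) {
        abort(sprintf("phantom %d: neither center nor radial distance given", ph$id))
      }
      ok <- FALSE
      for (att in seq_len(2000L)) {
        dir0 <- runif_direction()
        ctr <- cc + dir0 * ph$radial_distance_um
        dir_chain <- if (ph$shape == "chain") runif_direction() else dir0
        spheres <- phantom_spheres(ph, ctr, dir_chain)
        if (fits_cell(spheres) && clears(spheres)) {
          ph$center_um <- ctr; dir <- dir_chain; ok <- TRUE; break
        }
      }
      if (!ok) abort(sprintf("phantom %d: could not place without collisions", ph$id))
    } else {
      ctr <- ph$center_um
      if (ph$shape == "chain") dir <- runif_direction()
      spheres <- phantom_spheres(ph, ctr, dir)
      if (!fits_cell(spheres)) {
        abort(sprintf("phantom %d lies (partly) outside the cell", ph$id))
      }
    }
    placed <- c(placed, phantom_spheres(ph, ph$center_um, dir))
    idx <- rasterize_phantom(ph, spec, direction = dir)
    if (length(idx) == 0L) {
      warn(sprintf("phantom %d rasterized to zero voxels; dropped from truth", ph$id))
      next
    }
    for (ch in names(ph$channels)) {
      if (!ch %in% spec$channels) next
      fields[[ch]][idx] <- fields[[ch]][idx] + ph$channels[[ch]]
    }
    own <- idx[labels[idx] == 0L]   # earlier phantoms keep contested voxels
    if (length(own) == 0L) {
      warn(sprintf("phantom %d fully occluded by earlier phantoms; dropped from truth", ph$id))
      next
    }
    labels[own] <- ph$id
    vox_vol <- prod(vs)
    zi <- (own - 1L) %% dims[1] + 1L
    yi <- ((own - 1L) %/% dims[1]) %% dims[2] + 1L
    xi <- (own - 1L) %/% (dims[1] * dims[2]) + 1L
    cen <- c(mean(zi - 0.5) * vs[1], mean(yi - 0.5) * vs[2], mean(xi - 0.5) * vs[3])
    vol <- length(own) * vox_vol
    deq <- (6 * vol / pi)^(1 / 3)
    radial <- sqrt(sum((cen - cc)^2))
    memb <- stats::setNames(spec$channels %in% names(ph$channels)[ph$channels > 0],
                            spec$channels)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = ph$id, shape = ph$shape, voxel_count = length(own),
      volume_um3 = vol, equivalent_diameter_um = deq,
      centroid_z_um = cen[1], centroid_y_um = cen[2], centroid_x_um = cen[3],
      radial_distance_um = radial,
      distal_distance_um = radial + deq / 2,
      !!!as.list(memb))
  }
  truth_table <- if (length(rows)) dplyr::arrange(dplyr::bind_rows(rows), .data$id) else
    tibble::tibble(id = integer(), shape = character(), voxel_count = integer(),
                   volume_um3 = numeric(), equivalent_diameter_um = numeric(),
                   centroid_z_um = numeric(), centroid_y_um = numeric(),
                   centroid_x_um = numeric(), radial_distance_um = numeric(),
                   distal_distance_um = numeric())
  dim(labels) <- dims

  sig_vox <- spec$psf_sigma_um / vs
  per_channel <- function(x) {
    if (is.null(names(x))) stats::setNames(rep(x[1], length(spec$channels)),
                                           spec$channels)
    else stats::setNames(ifelse(spec$channels %in% names(x),
                                x[spec$channels], 0), spec$channels)
  }
  bg <- per_channel(spec$background_counts)
  cyt <- per_channel(spec$cytosol_counts)
  cell_idx <- NULL
  if (any(cyt > 0)) {
    zc2 <- (((seq_len(dims[1]) - 0.5) * vs[1]) - cc[1])^2
    yc2 <- (((seq_len(dims[2]) - 0.5) * vs[2]) - cc[2])^2
    xc2 <- (((seq_len(dims[3]) - 0.5) * vs[3]) - cc[3])^2
    cell_idx <- which(outer(outer(zc2, yc2, `+`), xc2, `+`) <= cell_r^2)
  }
  voxels <- array(0, c(dims[1], length(spec$channels), dims[2], dims[3]))
  for (ci in seq_along(spec$channels)) {
    ch <- spec$channels[ci]
    f <- fields[[ch]]
    if (cyt[[ch]] > 0) f[cell_idx] <- f[cell_idx] + cyt[[ch]]
    dim(f) <- dims
    if (any(sig_vox > 0)) {
      f <- cpp_blur3d(f, dims, sig_vox[1], sig_vox[2], sig_vox[3])
    }
    lambda <- f + bg[[ch]]
    img <- if (spec$poisson) stats::rpois(n, lambda) else lambda
    if (spec$read_noise_sd > 0) img <- img + stats::rnorm(n, 0, spec$read_noise_sd)
    img <- pmax(img, 0)
    voxels[, ci, , ] <- img
  }
  stack <- image_stack(voxels, vs, channels = spec$channels)
  structure(list(stack = stack,
                 truth = list(labels = labels, table = truth_table),
                 spec = spec),
            class = "elysa_scene")
}

#' @export
print.elysa_scene <- function(x, ...) {
  cat("<elysa_scene>\n")
  print(x$stack)
  cat(sprintf("  ground truth: %d object(s)\n", nrow(x$truth$table)))
  invisible(x)
}

# Draw channel memberships: exactly round(rate * n) phantoms per partner,
# sampled without replacement, so the programmed rate is realized exactly
# (up to rounding).
assign_memberships <- function(n, partners, rate, intensity) {
  memb <- matrix(FALSE, n, length(partners), dimnames = list(NULL, partners))
  for (p in partners) {
    k <- round(rate * n)
    if (k > 0) memb[sample.int(n, k), p] <- TRUE
  }
  memb
}

#' Stage-preset synthetic scenes
#'
#' Builds a [scene_spec()] emulating the organellar size/placement regimes of
#' four developmental stages. GV-like scenes carry many small (0.2-0.8 um)
#' assemblies plus a few large ones placed medially (distal distance < 25 um);
#' MII-like scenes carry fewer small structures and several large (3-7 um)
#' assemblies placed so that their distal distance exceeds 30 um (peripheral);
#' early/late 2-cell scenes replace the large assemblies with 1-3 um
#' structures, the early stage additionally carrying one chain-of-spheres
#' assembly emulating the transient concatenated morphology at division.
#' All scenes use the 81-plane / dz = 1 um acquisition grid, a 75-um cell,
#' the LAMP1 channel on every phantom and RAB5/LC3 on a 30% subset each.
#'
#' @param stage `"GV"`, `"MII"`, `"E2C"` or `"L2C"`.
#' @param seed integer seed; the same stage and seed give an identical spec.
#' @param partner_rate fraction of phantoms carrying each partner channel.
#' @return a [scene_spec()].
#' @export
preset_stage_scene <- function(stage = c("GV", "MII", "E2C", "L2C"), seed = 1L,
                               partner_rate = 0.3) {
  stage <- match.arg(stage)
  seed <- as.integer(seed)
  set.seed(seed)
  intens <- 2000
  mk <- function(d, radial) list(d = d, radial = radial, shape = "sphere")
  ph <- list()
  add_spheres <- function(ph, n, dfun, rfun) {
    for (i in seq_len(n)) {
      d <- dfun()
      ph[[length(ph) + 1L]] <- mk(d, rfun(d))
    }
    ph
  }
  if (stage == "GV") {
    ph <- add_spheres(ph, 120, function() stats::runif(1, 0.2, 0.8),
                      function(d) stats::runif(1, 2, 33))
    ph <- add_spheres(ph, 8, function() stats::runif(1, 4, 5.5),
                      function(d) stats::runif(1, 6, 23.5 - d / 2))
  } else if (stage == "MII") {
    # medium structures kept clear of the 25/30-um zone boundaries
    ph <- add_spheres(ph, 6, function() stats::runif(1, 3, 4),
                      function(d) stats::runif(1, 6, 22 - d / 2))
    ph <- add_spheres(ph, 6, function() stats::runif(1, 3, 4),
                      function(d) stats::runif(1, 31.5 - d / 2, 36.5 - d / 2))
    ph <- add_spheres(ph, 12, function() stats::runif(1, 4, 7),
                      function(d) stats::runif(1, 31.5 - d / 2, 36.3 - d / 2))
    ph <- add_spheres(ph, 1, function() stats::runif(1, 3, 4),
                      function(d) stats::runif(1, 6, 22 - d / 2))
  } else if (stage == "E2C") {
    ph <- add_spheres(ph, 60, function() stats::runif(1, 0.2, 0.8),
                      function(d) stats::runif(1, 2, 33))
    ph <- add_spheres(ph, 10, function() stats::runif(1, 1, 3),
                      function(d) stats::runif(1, 4, 33))
    ph[[length(ph) + 1L]] <- list(shape = "chain", d = 6,
                                  radial = stats::runif(1, 12, 18))
  } else {
    ph <- add_spheres(ph, 50, function() stats::runif(1, 0.2, 0.8),
                      function(d) stats::runif(1, 2, 33))
    ph <- add_spheres(ph, 8, function() stats::runif(1, 1, 3),
                      function(d) stats::runif(1, 4, 33))
  }
  n <- length(ph)
  memb <- assign_memberships(n, c("RAB5", "LC3"), partner_rate, intens)
  phantoms <- vector("list", n)
  for (i in seq_len(n)) {
    chans <- c(LAMP1 = intens)
    if (memb[i, "RAB5"]) chans <- c(chans, RAB5 = intens)
    if (memb[i, "LC3"]) chans <- c(chans, LC3 = intens)
    phantoms[[i]] <- if (ph[[i]]$shape == "chain") {
      phantom_spec(i, "chain", chain_diameters_um = rep(ph[[i]]$d, 4),
                   chain_overlap = 0.25,
                   radial_distance_um = ph[[i]]$radial, channels = chans)
    } else {
      phantom_spec(i, "sphere", diameter_um = ph[[i]]$d,
                   radial_distance_um = ph[[i]]$radial, channels = chans)
    }
  }
  scene_spec(grid_shape = c(81L, 256L, 256L), voxel_size_um = c(1, 0.35, 0.35),
             cell_diameter_um = 75, phantoms = phantoms,
             channels = c("LAMP1", "RAB5", "LC3"),
             psf_sigma_um = c(1, 0.35, 0.35), background_counts = 100,
             cytosol_counts = c(LAMP1 = 300, RAB5 = 150, LC3 = 150),
             read_noise_sd = 10, seed = seed)
}

#' Preset two-channel acidification scene
#'
#' A 41-plane / dz = 2 um scene with one structure per programmed
#' acidity ratio: each structure emits `ratio * base` counts in the
#' LysoTracker (numerator) channel and `base` counts in the LysoSensor
#' (denominator) channel, so the background-corrected Tracker/Sensor ratio
#' image should recover the programmed values.
#'
#' @param seed integer seed.
#' @param ratios programmed per-structure ratios.
#' @param base_counts denominator-channel mean photon count.
#' @return a [scene_spec()] whose phantom ids are ordered as `ratios`.
#' @export
preset_ratio_scene <- function(seed = 1L, ratios = c(0.5, 1, 3),
                               base_counts = 2000) {
  seed <- as.integer(seed)
  set.seed(seed)
  diam <- c(6, rep(3, max(0, length(ratios) - 1)))  # one assembly-sized, rest puncta-like
  phantoms <- vector("list", length(ratios))
  for (i in seq_along(ratios)) {
    phantoms[[i]] <- phantom_spec(
      i, "sphere", diameter_um = diam[i],
      radial_distance_um = stats::runif(1, 6, 14),
      channels = c(LysoTracker = ratios[i] * base_counts,
                   LysoSensor = base_counts))
  }
  scene_spec(grid_shape = c(41L, 128L, 128L), voxel_size_um = c(2, 0.35, 0.35),
             cell_diameter_um = 40, phantoms = phantoms,
             channels = c("LysoTracker", "LysoSensor"),
             psf_sigma_um = c(1, 0.35, 0.35), background_counts = 50,
             read_noise_sd = 5, clearance_um = 2, seed = seed)
}
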