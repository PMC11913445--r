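test_that("background estimation averages the per-region means", {
  img <- matrix(0, 20, 20)
  img[1:2, 1:2] <- 10; img[1:2, 19:20] <- 12
  img[19:20, 1:2] <- 14; img[19:20, 19:20] <- 16
  regions <- list(c(1, 2, 1, 2), c(1, 2, 19, 20), c(19, 20, 1, 2),
                  c(19, 20, 19, 20))
  expect_equal(estimate_background(img, regions), 13)
  expect_equal(estimate_background(matrix(5, 8, 8), list(c(2, 4, 2, 4))), 5)
  expect_error(estimate_background(img, list()), "region")
  expect_error(estimate_background(img, list(c(0, 2, 1, 2))), "bounds")
})

test_that("background estimate on pure-background render is unbiased", {
  sp <- scene_spec(grid_shape = c(6L, 64L, 64L), voxel_size_um = c(1, 0.5, 0.5),
                   cell_diameter_um = 5, phantoms = list(), channels = "LAMP1",
                   background_counts = 10, read_noise_sd = 0,
                   psf_sigma_um = c(0, 0, 0), seed = 3)
  img <- get_channel(render_scene(sp)$stack, 1)
  regions <- list(c(1, 8, 1, 8), c(1, 8, 57, 64), c(57, 64, 1, 8),
                  c(57, 64, 57, 64))
  n_px <- 4 * 8 * 8 * 6
  expect_lt(abs(estimate_background(img, regions) - 10), 3 * sqrt(10 / n_px))
})

test_that("thresholding is strict and monotone", {
  a <- array(600, c(2, 3, 3))
  expect_false(any(threshold_stack(a, 600)))
  set.seed(4)
  r <- array(runif(4 * 10 * 10, 0, 2000), c(4, 10, 10))
  expect_true(all(which(threshold_stack(r, 1200)) %in% which(threshold_stack(r, 600))))
  expect_error(threshold_stack(r, 0), "positive")
})

test_that("noiseless phantoms threshold back to the exact rasterization", {
  sc <- render_scene(small_noiseless_scene())
  mask <- threshold_stack(get_channel(sc$stack, 1), 1000)
  expect_identical(unname(mask), unname(sc$truth$labels > 0))
})

test_that("connectivity definitions separate corner-sharing voxels", {
  m <- array(FALSE, c(3, 3, 3))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
  expect_equal(max(label_components(m, 26)), 1L)
  expect_equal(max(label_components(m, 18)), 2L)
  expect_equal(max(label_components(m, 6)), 2L)
  single <- array(FALSE, c(2, 2, 2)); single[1, 1, 1] <- TRUE
  lab <- label_components(single, 26)
  expect_equal(sum(lab == 1L), 1L)
  expect_equal(max(label_components(array(FALSE, c(2, 2, 2)), 6)), 0L)
})

test_that("component labeling matches the flood-fill oracle on random volumes", {
  set.seed(7)
  for (i in 1:15) {
    m <- array(runif(12^3) < 0.2, c(12, 12, 12))
    for (conn in c(6, 18, 26)) {
      expect_identical(canonical_labels(label_components(m, conn)),
                       canonical_labels(flood_fill_oracle(m, conn)))
    }
  }
})

test_that("object measurement follows the voxel-center conventions", {
  # 3x3x3 cube at voxel size (1, 0.4, 0.4): volume 27 * 0.16 = 4.32
  lab <- array(0L, c(5, 5, 5)); lab[2:4, 2:4, 2:4] <- 1L
  tab <- measure_objects(lab, array(1, c(5, 5, 5)), c(1, 0.4, 0.4))
  expect_equal(tab$volume_um3, 27 * 0.16)
  # single voxel at (1,1,1), unit voxels: centroid at (0.5, 0.5, 0.5)
  lab1 <- array(0L, c(2, 2, 2)); lab1[1, 1, 1] <- 1L
  t1 <- measure_objects(lab1, array(2, c(2, 2, 2)), c(1, 1, 1))
  expect_equal(unlist(t1[1, c("centroid_z_um", "centroid_y_um", "centroid_x_um")],
                      use.names = FALSE), c(0.5, 0.5, 0.5))
  expect_equal(t1$integrated_intensity, 2)
  expect_equal(t1$mean_intensity, 2)
  expect_error(measure_objects(lab1, array(0, c(3, 3, 3)), c(1, 1, 1)), "shape")
})

test_that("a digitized 6-um sphere measures within 2% of its analytic volume", {
  dims <- c(40L, 40L, 40L); vs <- c(0.2, 0.2, 0.2)
  idx <- brute_sphere_voxels(c(4, 4, 4), 6, dims, vs)
  lab <- array(0L, dims); lab[idx] <- 1L
  tab <- measure_objects(lab, array(1, dims), vs)
  expect_lt(abs(tab$volume_um3 - 113.0973) / 113.0973, 0.02)
  expect_lt(abs(tab$equivalent_diameter_um - 6) / 6, 0.01)
})

test_that("volume filtering keeps (min, max] and can exclude boundary objects", {
  tab <- tibble::tibble(label = 1:3, volume_um3 = c(0.1, 4999, 5001),
                        centroid_y_um = c(5, 5, 5), centroid_x_um = c(5, 5, 5))
  kept <- filter_objects(tab, c(0, 5000))
  expect_equal(kept$volume_um3, c(0.1, 4999))
  expect_equal(nrow(filter_objects(tab, c(0, Inf))), 3L)
  # PM-hugging object: centroid near the mask boundary
  mask <- matrix(FALSE, 40, 40)
  mask[cbind(rep(1:40, 40), rep(1:40, each = 40))] <-
    (rep(1:40, 40) - 20.5)^2 + (rep(1:40, each = 40) - 20.5)^2 <= 15^2
  geom <- structure(list(cell_mask = mask, voxel_size_um = c(1, 1, 1)),
                    class = "cell_geometry")
  tab2 <- tibble::tibble(label = 1:2, volume_um3 = c(10, 10),
                         centroid_y_um = c(20.5, 20.5),
                         centroid_x_um = c(20.5, 34.5))
  p0 <- segmentation_params(boundary_exclusion_um = 0)
  p2 <- segmentation_params(boundary_exclusion_um = 2)
  expect_equal(nrow(filter_objects(tab2, p0, geom)), 2L)
  expect_equal(filter_objects(tab2, p2, geom)$label, 1L)
})

test_that("volume totals are conserved through labeling and measurement", {
  set.seed(9)
  m <- array(runif(10 * 14 * 14) < 0.15, c(10, 14, 14))
  vs <- c(1, 0.4, 0.4)
  lab <- label_components(m, 26)
  tab <- measure_objects(lab, array(1, dim(m)), vs)
  expect_equal(sum(tab$volume_um3), sum(m) * prod(vs))
  expect_equal(sum(tab$voxel_count), sum(m))
})

test_that("object count and total volume are non-increasing in threshold", {
  sc <- render_scene(preset_stage_scene("L2C", seed = 4))
  img <- get_channel(sc$stack, "LAMP1")
  prev_n <- Inf; prev_v <- Inf
  for (th in c(600, 900, 1200)) {
    mask <- threshold_stack(img, th)
    lab <- label_components(mask, 26)
    tab <- measure_objects(lab, img, sc$stack$voxel_size_um)
    expect_lte(sum(tab$volume_um3), prev_v)
    prev_v <- sum(tab$volume_um3)
    prev_n <- nrow(tab)
  }
})

test_that("cell geometry finds the center plane and 3D center", {
  # signal spanning z-planes 10..70 -> center plane 40
  a <- array(0, c(81, 30, 30))
  a[10:70, 10:20, 10:20] <- 1000
  geom <- find_cell_geometry(a, c(1, 1, 1), threshold = 500)
  expect_equal(geom$center_plane_z, 40L)
  # spherical phantom cell: center recovered within one voxel per axis
  sp <- scene_spec(grid_shape = c(40L, 60L, 60L), voxel_size_um = c(1, 0.5, 0.5),
                   cell_diameter_um = 26, phantoms = list(), channels = "LAMP1",
                   cytosol_counts = 300, background_counts = 50,
                   read_noise_sd = 5, seed = 6)
  sc <- render_scene(sp)
  geom2 <- find_cell_geometry(get_channel(sc$stack, 1), sp$voxel_size_um)
  truth_center <- sp$grid_shape * sp$voxel_size_um / 2
  expect_true(all(abs(geom2$center_um - truth_center) <= sp$voxel_size_um))
  expect_true(geom2$cell_mask[round(truth_center[2] / 0.5),
                              round(truth_center[3] / 0.5)])
  expect_error(find_cell_geometry(array(0, c(4, 4, 4)), c(1, 1, 1),
                                  threshold = 10), "signal")
})

test_that("noiseless scenes segment to exactly the ground-truth object count", {
  sc <- render_scene(small_noiseless_scene())
  seg <- segment_objects(sc$stack,
                         segmentation_params(blur_sigma_px = 0,
                                             background_mode = "none"),
                         channel = "LAMP1")
  expect_equal(nrow(seg$table), nrow(sc$truth$table))
  expect_equal(sum(seg$table$voxel_count), sum(sc$truth$labels > 0))
})
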