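test_that("sphere rasterization matches the brute-force point-in-sphere oracle", {
  sp <- scene_spec(grid_shape = c(20L, 20L, 20L), voxel_size_um = c(0.2, 0.2, 0.2),
                   cell_diameter_um = 3.5, phantoms = list(), seed = 1)
  ctr <- c(2.1, 2.1, 2.1)  # a voxel center on the 0.2-um grid
  ph <- phantom_spec(1, "sphere", diameter_um = 1, center_um = ctr)
  idx <- rasterize_phantom(ph, sp)
  expect_setequal(idx, brute_sphere_voxels(ctr, 1, sp$grid_shape, sp$voxel_size_um))
  # digitization bias at this resolution: the brute-force count is 81 voxels
  # (0.648 um^3), +24% over pi/6 -- a boundary-heavy configuration; the
  # rasterizer must reproduce exactly that count
  expect_length(idx, 81L)
  vol <- length(idx) * 0.2^3
  expect_lt(abs(vol - pi / 6) / (pi / 6), 0.25)
})

test_that("a sub-voxel sphere centered on a voxel center occupies exactly one voxel", {
  sp <- scene_spec(grid_shape = c(10L, 10L, 10L), voxel_size_um = c(0.5, 0.5, 0.5),
                   cell_diameter_um = 4, phantoms = list(), seed = 1)
  ph <- phantom_spec(1, "sphere", diameter_um = 0.3, center_um = c(2.25, 2.25, 2.25))
  expect_length(rasterize_phantom(ph, sp), 1L)
})

test_that("a two-sphere chain rasterizes to a single 26-connected component", {
  sp <- scene_spec(grid_shape = c(40L, 40L, 40L), voxel_size_um = c(0.35, 0.35, 0.35),
                   cell_diameter_um = 13, phantoms = list(), seed = 1)
  ph <- phantom_spec(1, "chain", chain_diameters_um = c(2, 2), chain_overlap = 0.25,
                     center_um = c(7, 7, 7))
  idx <- rasterize_phantom(ph, sp, direction = c(0, 0, 1))
  mask <- array(FALSE, sp$grid_shape)
  mask[idx] <- TRUE
  expect_equal(max(flood_fill_oracle(mask, 26)), 1L)
})

test_that("rasterized sphere volume converges to pi/6 d^3 as voxels shrink", {
  d <- 2
  err <- vapply(c(0.4, 0.2, 0.1), function(h) {
    n <- ceiling(3.2 / h)
    sp <- scene_spec(grid_shape = rep(n, 3), voxel_size_um = rep(h, 3),
                     cell_diameter_um = 3, phantoms = list(), seed = 1)
    ctr <- rep(n * h / 2, 3)
    ph <- phantom_spec(1, "sphere", diameter_um = d, center_um = ctr)
    abs(length(rasterize_phantom(ph, sp)) * h^3 - pi / 6 * d^3) / (pi / 6 * d^3)
  }, numeric(1))
  expect_true(all(diff(err) < 0))   # strictly improving
  expect_lt(err[3], 0.02)
})

test_that("a phantom that would leave the grid raises a placement error naming it", {
  sp <- scene_spec(grid_shape = c(10L, 10L, 10L), voxel_size_um = c(1, 1, 1),
                   cell_diameter_um = 9, phantoms = list(), seed = 1)
  ph <- phantom_spec(7, "sphere", diameter_um = 4, center_um = c(1, 5, 5))
  expect_error(rasterize_phantom(ph, sp), "phantom 7")
})

test_that("rendering is bit-identical under the same spec and seed", {
  sp <- scene_spec(grid_shape = c(20L, 40L, 40L), voxel_size_um = c(1, 0.5, 0.5),
                   cell_diameter_um = 18,
                   phantoms = list(phantom_spec(1, "sphere", diameter_um = 3,
                                                radial_distance_um = 4)),
                   seed = 42)
  s1 <- render_scene(sp)
  s2 <- render_scene(sp)
  expect_identical(s1$stack$voxels, s2$stack$voxels)
  expect_identical(s1$truth$labels, s2$truth$labels)
})

test_that("a pure-background render has the programmed Poisson mean", {
  sp <- scene_spec(grid_shape = c(10L, 40L, 40L), voxel_size_um = c(1, 0.5, 0.5),
                   cell_diameter_um = 8, phantoms = list(), channels = "LAMP1",
                   background_counts = 10, read_noise_sd = 0,
                   psf_sigma_um = c(0, 0, 0), seed = 5)
  sc <- render_scene(sp)
  n <- prod(sp$grid_shape)
  se <- sqrt(10 / n)
  expect_lt(abs(mean(sc$stack$voxels) - 10), 3 * se)
})

test_that("noiseless rendering recovers the ground-truth label volume by thresholding", {
  sc <- render_scene(small_noiseless_scene())
  img <- get_channel(sc$stack, "LAMP1")
  expect_identical(unname(img > 1000), unname(sc$truth$labels > 0))
})

test_that("ground-truth tables and label volumes are mutually consistent", {
  sc <- render_scene(preset_stage_scene("L2C", seed = 2))
  tab <- sc$truth$table
  labs <- sc$truth$labels
  expect_setequal(tab$id, sort(unique(labs[labs > 0])))
  vox_vol <- prod(sc$stack$voxel_size_um)
  for (i in sample(nrow(tab), 10)) {
    expect_equal(tab$volume_um3[i], sum(labs == tab$id[i]) * vox_vol)
  }
})

test_that("stage presets encode the stage-dependent placement regimes", {
  # MII: at least 80% of >4-um phantoms are peripheral (distal > 30 um);
  # GV has more 0.2-0.8 um phantoms than MII. Checked on the generated
  # specs over several seeds.
  for (seed in 1:10) {
    mii <- preset_stage_scene("MII", seed = seed)
    gv <- preset_stage_scene("GV", seed = seed)
    distal <- vapply(mii$phantoms, function(p)
      p$radial_distance_um + p$diameter_um / 2, numeric(1))
    d <- vapply(mii$phantoms, function(p) p$diameter_um, numeric(1))
    expect_gte(mean(distal[d > 4] > 30), 0.8)
    n_small <- function(sp) sum(vapply(sp$phantoms, function(p)
      !is.null(p$diameter_um) && p$diameter_um >= 0.2 && p$diameter_um <= 0.8,
      logical(1)))
    expect_gt(n_small(gv), n_small(mii))
  }
})

test_that("stage presets are deterministic in stage and seed", {
  expect_identical(preset_stage_scene("GV", seed = 9),
                   preset_stage_scene("GV", seed = 9))
  expect_error(preset_stage_scene("XX", seed = 1))
})

test_that("scene and phantom validation rejects bad inputs", {
  expect_error(phantom_spec(1, "sphere", diameter_um = -1), "positive")
  expect_error(phantom_spec(1, "chain", chain_diameters_um = c(1, 1),
                            chain_overlap = 0.7), "overlap")
  expect_error(scene_spec(grid_shape = c(0, 10, 10)), "positive")
  expect_error(scene_spec(grid_shape = c(50, 50, 50),
                          voxel_size_um = c(1, 0.2, 0.2),
                          cell_diameter_um = 75), "fit")
  ph <- list(phantom_spec(1, "sphere", diameter_um = 1, radial_distance_um = 0),
             phantom_spec(1, "sphere", diameter_um = 1, radial_distance_um = 2))
  expect_error(scene_spec(phantoms = ph), "unique")
})
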