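blanks_for <- function(d, s = 6L) {
  list(c(1L, s, 1L, s), c(1L, s, d[2] - s + 1L, d[2]),
       c(d[1] - s + 1L, d[1], 1L, s), c(d[1] - s + 1L, d[1], d[2] - s + 1L, d[2]))
}

test_that("uniform channels give a uniform ratio", {
  a <- matrix(200, 40, 40); b <- matrix(100, 40, 40)
  # corners are true background (zero) so nothing is subtracted from signal
  a2 <- a; b2 <- b
  for (r in blanks_for(dim(a))) { a2[r[1]:r[2], r[3]:r[4]] <- 0; b2[r[1]:r[2], r[3]:r[4]] <- 0 }
  ri2 <- make_ratio_image(a2, b2, blanks_for(dim(a)), floor = 1)
  inner <- ri2$values[15:25, 15:25]
  expect_true(all(ri2$valid_mask[15:25, 15:25]))
  expect_true(all(inner == 2))
})

test_that("per-channel background subtraction recovers the true ratio", {
  d <- c(40, 40)
  a <- matrix(50, d[1], d[2]); b <- matrix(20, d[1], d[2])
  a[15:25, 15:25] <- 150   # background 50 + signal 100
  b[15:25, 15:25] <- 120   # background 20 + signal 100
  ri <- make_ratio_image(a, b, blanks_for(d), floor = 1)
  expect_true(all(abs(ri$values[15:25, 15:25] - 1) < 1e-12))
  expect_equal(ri$background_a, 50)
  expect_equal(ri$background_b, 20)
  # outside the structure the corrected denominator is 0 -> invalid
  expect_false(any(ri$valid_mask[1:10, 1:10]))
})

test_that("an unreachable floor yields a warning-carrying all-invalid result", {
  a <- matrix(10, 20, 20); b <- matrix(10, 20, 20)
  expect_warning(ri <- make_ratio_image(a, b, blanks_for(c(20, 20)), floor = 1e6),
                 "valid")
  expect_false(any(ri$valid_mask))
  expect_false(is.null(ri$warning))
})

test_that("ratio scale equivariance and channel-swap inversion hold", {
  set.seed(16)
  d <- c(30, 30)
  b <- matrix(runif(900, 50, 100), d[1], d[2])
  a <- matrix(runif(900, 50, 100), d[1], d[2])
  bl <- blanks_for(d)
  for (r in bl) { a[r[1]:r[2], r[3]:r[4]] <- 0; b[r[1]:r[2], r[3]:r[4]] <- 0 }
  r1 <- make_ratio_image(a, b, bl, floor = 1)
  r3 <- make_ratio_image(3 * a, b, bl, floor = 1)
  expect_equal(r3$values[r1$valid_mask & r3$valid_mask],
               3 * r1$values[r1$valid_mask & r3$valid_mask])
  swapped <- make_ratio_image(b, a, bl, floor = 1)
  both <- r1$valid_mask & swapped$valid_mask & r1$values > 0
  expect_equal(swapped$values[both], 1 / r1$values[both], tolerance = 1e-12)
})

test_that("per-object ratio statistics use valid pixels only", {
  vals <- matrix(2, 10, 10)
  valid <- matrix(TRUE, 10, 10)
  valid[, 6:10] <- FALSE
  vals[!valid] <- NA
  ri <- structure(list(values = vals, valid_mask = valid, background_a = 0,
                       background_b = 0, floor = 1, warning = NULL),
                  class = "ratio_image")
  labs <- matrix(0L, 10, 10)
  labs[2:4, 2:4] <- 1L        # fully valid
  labs[2:4, 7:9] <- 2L        # fully invalid
  por <- per_object_ratio(ri, labs)
  expect_equal(por$median_ratio[por$label == 1], 2)
  expect_true(por$flagged[por$label == 2])
  expect_true(is.na(por$median_ratio[por$label == 2]))
})

test_that("programmed acidity ratios are recovered from a rendered two-channel scene", {
  ratios <- c(0.5, 1, 3)
  sc <- render_scene(preset_ratio_scene(seed = 21, ratios = ratios))
  a <- get_channel(sc$stack, "LysoTracker")
  b <- get_channel(sc$stack, "LysoSensor")
  d <- dim(a)[2:3]
  bl <- list(c(1L, 16L, 1L, 16L), c(1L, 16L, d[2] - 15L, d[2]),
             c(d[1] - 15L, d[1], 1L, 16L), c(d[1] - 15L, d[1], d[2] - 15L, d[2]))
  ri <- make_ratio_image(a, b, bl)
  labs2d <- apply(sc$truth$labels, c(2, 3), max)
  por <- per_object_ratio(ri, labs2d)
  for (i in seq_along(ratios)) {
    expect_lt(abs(por$median_ratio[por$label == i] - ratios[i]) / ratios[i], 0.05)
  }
  # the small high-ratio puncta sit above the large low-ratio assembly
  expect_gt(por$median_ratio[por$label == 3], por$median_ratio[por$label == 1])
})

test_that("line profiles follow constant, ramp and symmetry references", {
  const <- matrix(4, 20, 20)
  pr <- line_profile(const, c(5, 2), c(5, 18), n_samples = 30,
                     pixel_size_um = c(1, 1))
  expect_true(all(pr$intensity == 4))
  expect_equal(pr$distance_um[1], 0)
  expect_equal(max(pr$distance_um), 16)
  ramp <- matrix(rep(1:30, each = 20), 20, 30, byrow = FALSE)
  pr2 <- line_profile(ramp, c(10, 2), c(10, 28), n_samples = 40,
                      pixel_size_um = c(1, 1))
  expect_lt(max(abs(diff(diff(pr2$intensity)))), 1e-9)  # piecewise-constant slope
  expect_error(line_profile(const, c(-1, 5), c(5, 5)), "outside")
})

test_that("a profile across a rendered sphere peaks at its center", {
  sc <- render_scene(preset_ratio_scene(seed = 3, ratios = 2))
  img <- project(get_channel(sc$stack, "LysoSensor"), "mean")
  tt <- sc$truth$table
  vs <- sc$stack$voxel_size_um
  c_y <- tt$centroid_y_um[1]; c_x <- tt$centroid_x_um[1]
  pr <- line_profile(img, c(c_y, c_x - 6), c(c_y, c_x + 6), n_samples = 121,
                     pixel_size_um = vs[2:3])
  # symmetric dome: intensity-weighted center of the background-corrected
  # profile sits at the sphere center (profile midpoint)
  w <- pmax(pr$intensity - min(pr$intensity), 0)
  com <- sum(pr$distance_um * w) / sum(w)
  expect_lt(abs(com - 6), 0.2)
})

test_that("fire rendering maps range ends to the LUT ends and invalid to black", {
  vals <- matrix(c(0, 5, 10, NA), 2, 2)
  valid <- !is.na(vals)
  ri <- structure(list(values = vals, valid_mask = valid, background_a = 0,
                       background_b = 0, floor = 1, warning = NULL),
                  class = "ratio_image")
  rgb <- export_fire_lut(ri, range = c(0, 10))
  expect_equal(rgb[1, 1, ], c(0, 0, 0))      # range minimum -> first color
  expect_equal(rgb[1, 2, ], c(1, 1, 1))      # range maximum -> last color
  expect_equal(rgb[2, 2, ], c(0, 0, 0))      # invalid -> black
  expect_identical(rgb, export_fire_lut(ri, range = c(0, 10)))
  expect_error(export_fire_lut(ri, range = c(5, 5)), "range")
})
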