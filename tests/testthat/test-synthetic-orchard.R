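# Synthetic orchard generator: geometry, ground truth, determinism.

test_that("a treeless scene is all ground with zero volume everywhere", {
  sc <- generate_orchard(extent = c(9, 9), gsd = 0.05,
                         trees = data.frame(), weed_noise_sd = 0,
                         point_density = 0, make_rgb = FALSE, seed = 1)
  expect_true(all(sc$truth_mask$labels == MASK_GROUND))
  expect_true(all(sc$true_volumes$volume == 0))
  expect_equal(nrow(sc$true_volumes), 4)
})

test_that("rasterized half-ellipsoid volume matches the closed form within 2% at fine resolution", {
  tree <- data.frame(tree_id = 1L, base_x = 2, base_y = 2, trunk_height = 0,
                     a = 1, b = 1, c = 2, shape = "half_ellipsoid")
  sc <- generate_orchard(extent = c(4, 4), trees = tree, gsd = 0.01,
                         ground_slope = c(0, 0), weed_noise_sd = 0,
                         plot_side = 4, point_density = 0, make_rgb = FALSE,
                         seed = 1)
  analytic <- crown_closed_volume(1, 1, 2)   # (2/3) pi * 2 ~ 4.18879
  expect_equal(sum(sc$true_volumes$volume), analytic, tolerance = 0.02)
})

test_that("rasterization error decreases strictly as gsd is refined", {
  tree <- data.frame(tree_id = 1L, base_x = 2, base_y = 2, trunk_height = 0,
                     a = 1, b = 1, c = 2, shape = "half_ellipsoid")
  analytic <- crown_closed_volume(1, 1, 2)
  errs <- sapply(c(0.04, 0.02, 0.01), function(g) {
    sc <- generate_orchard(extent = c(4, 4), trees = tree, gsd = g,
                           ground_slope = c(0, 0), weed_noise_sd = 0,
                           plot_side = 4, point_density = 0, make_rgb = FALSE,
                           seed = 1)
    abs(sum(sc$true_volumes$volume) - analytic)
  })
  expect_true(all(diff(errs) < 0))
})

test_that("identical seed and parameters give a bit-identical scene", {
  args <- list(extent = c(6, 4.5), gsd = 0.03, seed = 42, point_density = 50)
  a <- do.call(generate_orchard, args)
  b <- do.call(generate_orchard, args)
  expect_identical(a$dsm$values, b$dsm$values)
  expect_identical(a$truth_mask$labels, b$truth_mask$labels)
  expect_identical(a$rgb$rgb, b$rgb$rgb)
  expect_identical(a$point_cloud, b$point_cloud)
  expect_identical(a$true_volumes, b$true_volumes)
  c_ <- do.call(generate_orchard, modifyList(args, list(seed = 43)))
  expect_false(identical(a$dsm$values, c_$dsm$values))
})

test_that("per-plot true volumes sum to the whole-scene canopy integral", {
  sc <- generate_orchard(extent = c(9, 9), gsd = 0.03, seed = 5,
                         point_density = 0, make_rgb = FALSE)
  # recompute per plot with the same mean-ground definition, independently
  plots <- partition_plots(sc$dsm, sc$plot_side)
  total <- 0
  for (k in seq_len(nrow(plots))) {
    w <- plots[k, ]
    v <- sc$dsm$values[(w$row_start + 1):w$row_stop,
                       (w$col_start + 1):w$col_stop]
    l <- sc$truth_mask$labels[(w$row_start + 1):w$row_stop,
                              (w$col_start + 1):w$col_stop]
    mg <- mean(v[l == MASK_GROUND])
    total <- total + sc$dsm$gsd^2 * sum(pmax(0, v[l == MASK_CANOPY] - mg))
  }
  expect_equal(sum(sc$true_volumes$volume), total, tolerance = 1e-12)
})

test_that("surface-sampled cloud points lie exactly on crown surfaces", {
  sc <- generate_orchard(extent = c(4.5, 4.5), gsd = 0.05, seed = 3,
                         point_density = 0, make_rgb = FALSE)
  pts <- sample_point_cloud(sc, density = 1e4, seed = 9)
  # each point must satisfy some tree's implicit surface equation
  sl <- sc$params$ground_slope
  resid <- rep(Inf, nrow(pts))
  for (k in seq_len(nrow(sc$trees))) {
    tr <- sc$trees[k, ]
    z0 <- sc$params$base_altitude + sl[1] * tr$base_x + sl[2] * tr$base_y +
      tr$trunk_height
    r <- abs(((pts[, 1] - tr$base_x) / tr$a)^2 +
             ((pts[, 2] - tr$base_y) / tr$b)^2 +
             ((pts[, 3] - z0) / tr$c)^2 - 1)
    resid <- pmin(resid, r)
  }
  expect_lt(max(resid), 1e-6)
  # count tracks density x surface area (rejection sampling, +-5%)
  area <- 0
  for (k in seq_len(nrow(sc$trees))) {
    tr <- sc$trees[k, ]
    # numerical area of the upper half-ellipsoid
    f <- function(th) {
      sapply(th, function(t) {
        integrate(function(ph) {
          ux <- sin(t) * cos(ph); uy <- sin(t) * sin(ph); uz <- cos(t)
          sqrt((tr$b * tr$c * ux)^2 + (tr$a * tr$c * uy)^2 +
               (tr$a * tr$b * uz)^2) * sin(t)
        }, 0, 2 * pi)$value
      })
    }
    area <- area + integrate(f, 0, pi / 2)$value
  }
  expect_equal(nrow(pts), 1e4 * area, tolerance = 0.05)
  expect_identical(pts, sample_point_cloud(sc, density = 1e4, seed = 9))
})

test_that("an empty scene yields an empty point cloud", {
  sc <- generate_orchard(extent = c(4.5, 4.5), gsd = 0.1, trees = data.frame(),
                         point_density = 0, make_rgb = FALSE, seed = 1)
  expect_equal(nrow(sample_point_cloud(sc, density = 100, seed = 1)), 0)
})

test_that("training tiles come from disjoint split regions and are reproducible", {
  sc <- generate_orchard(extent = c(13.5, 4.5), gsd = 0.05, seed = 2,
                         point_density = 0)
  tiles <- make_training_tiles(sc, tile_px = 30, n_train = 4, n_val = 2,
                               n_test = 3, seed = 7)
  expect_equal(nrow(tiles), 9)
  # split column ranges must not overlap
  hi <- tapply(tiles$col_stop, tiles$split, max)
  lo <- tapply(tiles$col_start, tiles$split, min)
  expect_lte(hi[["train"]], lo[["val"]])
  expect_lte(hi[["val"]], lo[["test"]])
  expect_identical(tiles, make_training_tiles(sc, tile_px = 30, n_train = 4,
                                              n_val = 2, n_test = 3, seed = 7))
  # materialized tile carries RGB + DSM channels and labels
  tl <- extract_tile(sc, tiles[1, ])
  expect_equal(dim(tl$dsm), c(30, 30))
  expect_equal(dim(tl$rgb), c(30, 30, 3))
  expect_equal(dim(tl$labels), c(30, 30))
  expect_true(all(tl$labels %in% c(MASK_GROUND, MASK_CANOPY)))
  # a 281 px tile at the survey gsd covers 4.496 m
  expect_equal(281 * 0.016, 4.496)
  expect_error(make_training_tiles(sc, tile_px = 200, n_train = 1, n_val = 1,
                                   n_test = 1, seed = 1), "narrower|fewer")
})

test_that("negative weed noise is rejected and overlapping trees max-combine", {
  expect_error(generate_orchard(extent = c(5, 5), weed_noise_sd = -1),
               "weed_noise_sd")
  trees <- data.frame(tree_id = 1:2, base_x = c(2, 2.5), base_y = c(2.5, 2.5),
                      trunk_height = c(0.5, 0.5), a = c(1, 1), b = c(1, 1),
                      c = c(2, 3), shape = "half_ellipsoid")
  sc <- generate_orchard(extent = c(5, 5), trees = trees, gsd = 0.05,
                         ground_slope = c(0, 0), weed_noise_sd = 0,
                         base_altitude = 0, point_density = 0,
                         make_rgb = FALSE, seed = 1)
  # apex of the taller crown wins where they overlap
  expect_equal(max(sc$dsm$values), 0.5 + 3, tolerance = 1e-3)
})

test_that("scene files round-trip through write_scene", {
  sc <- generate_orchard(extent = c(4.5, 4.5), gsd = 0.1, seed = 4,
                         point_density = 20)
  dir <- withr::local_tempdir()
  files <- write_scene(sc, dir)
  expect_true(all(file.exists(files)))
  dsm2 <- read_raster(file.path(dir, "dsm.asc"))
  expect_identical(dsm2$values, sc$dsm$values)
  msk2 <- read_mask(file.path(dir, "truth_mask.png"))
  expect_identical(unname(msk2$labels), unname(sc$truth_mask$labels))
  cl2 <- read_point_cloud(file.path(dir, "cloud.xyz"))
  expect_equal(unname(cl2), unname(sc$point_cloud))
  tv <- read.csv(file.path(dir, "truth_volumes.csv"))
  expect_equal(tv$volume, sc$true_volumes$volume)
})
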