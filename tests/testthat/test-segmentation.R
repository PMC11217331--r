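# Otsu thresholding, RANSAC plane fitting, and the per-plot backends.

test_that("Otsu splits two delta masses between them", {
  t <- otsu_threshold(c(rep(0, 50), rep(10, 50)))
  expect_gt(t, 0)
  expect_lte(t, 10)
  v <- c(rep(0, 50), rep(10, 50))
  expect_equal(sum(v > t), 50)
})

test_that("Otsu equals exhaustive between-class-variance maximization", {
  set.seed(7)
  v <- c(rnorm(1000, 0, 0.1), rnorm(1000, 3, 0.3))
  expect_identical(otsu_threshold(v, 256), oracle_otsu(v, 256))
  # across many histogram shapes: mixtures, unimodal, heavy ties
  for (s in 1:25) {
    set.seed(s)
    v <- switch(1 + s %% 4,
                c(rnorm(200, 0, 0.2), rnorm(300, 2, 0.5)),
                runif(500, 0, 5),
                c(rep(0.5, 400), rnorm(100, 4, 0.1)),
                rexp(500))
    for (bins in c(16, 256))
      expect_identical(otsu_threshold(v, bins), oracle_otsu(v, bins),
                       info = sprintf("seed %d bins %d", s, bins))
  }
})

test_that("Otsu rejects constant input", {
  expect_error(otsu_threshold(rep(1, 10)), class = "canovol_degenerate_histogram")
})

test_that("flat plots fall under the degenerate guard and become all ground", {
  r <- flat_raster(20, 20, value = 100, gsd = 0.25)
  m <- segment_otsu(r)
  expect_true(all(m$labels == MASK_GROUND))
  # noise below the roughness floor is still all ground
  set.seed(1)
  r2 <- elevation_raster(matrix(100 + rnorm(400, 0, 0.01), 20, 20), gsd = 0.25)
  expect_true(all(segment_otsu(r2)$labels == MASK_GROUND))
})

test_that("a half-low half-high plot thresholds exactly between the halves", {
  v <- cbind(matrix(0, 10, 5), matrix(3, 10, 5))
  m <- segment_otsu(elevation_raster(v, gsd = 1))
  expect_true(all(m$labels[, 1:5] == MASK_GROUND))
  expect_true(all(m$labels[, 6:10] == MASK_CANOPY))
})

test_that("OTSU mask matches truth on >= 99% of pixels of a synthetic plot", {
  # rough ground (SD ~0.05 m weeds) with crown pixels 1.5-4 m above it:
  # the elevation histogram is cleanly bimodal in this regime
  sc <- generate_orchard(extent = c(4.5, 4.5), gsd = 0.016, seed = 11,
                         trunk_height = c(1.5, 1.6),
                         crown_height = c(2.2, 2.4),
                         point_density = 0, make_rgb = FALSE)
  m <- segment_otsu(sc$dsm)
  agree <- mean(m$labels == sc$truth_mask$labels)
  expect_gte(agree, 0.99)
})

test_that("RANSAC recovers an exact plane with all points as inliers", {
  set.seed(2)
  pts <- cbind(runif(100), runif(100), 0)
  fit <- fit_plane_ransac(pts, iterations = 50, seed = 1)
  expect_equal(fit$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fit$offset, 0, tolerance = 1e-12)
  expect_equal(fit$inlier_count, 100L)
})

test_that("RANSAC matches the least-squares fit on the known inlier set under outliers", {
  set.seed(1)
  x <- runif(200, 0, 10); y <- runif(200, 0, 10)
  pts <- cbind(x, y, 0.1 * x + 0.2 * y + 5)
  out_idx <- 1:50
  pts[out_idx, 3] <- pts[out_idx, 3] + runif(50, 1, 4)
  fit <- fit_plane_ransac(pts, n_samples = 50, iterations = 500,
                          distance = 0.2, seed = 1)
  oracle <- oracle_tls_plane(pts[-out_idx, ])
  expect_equal(fit$normal, oracle$normal, tolerance = 1e-2)
  expect_equal(fit$offset, oracle$offset, tolerance = 1e-2)
  # inlier set identifies the true on-plane points
  expect_true(all(fit$inliers[-out_idx]))
  expect_false(any(fit$inliers[out_idx]))
})

test_that("RANSAC is deterministic under a seed and errors on degenerate input", {
  set.seed(3)
  pts <- cbind(runif(50), runif(50), runif(50, 0, 0.1))
  a <- fit_plane_ransac(pts, iterations = 100, seed = 5)
  b <- fit_plane_ransac(pts, iterations = 100, seed = 5)
  expect_identical(a$normal, b$normal)
  expect_identical(a$inliers, b$inliers)
  expect_error(fit_plane_ransac(pts[1:2, ]), class = "canovol_fit_failure")
  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_plane_ransac(line, iterations = 20, seed = 1),
               class = "canovol_fit_failure")
})

test_that("RANSAC backend labels a flat plot all ground", {
  r <- flat_raster(20, 20, value = 50, gsd = 0.25)
  cfg <- segmentation_config("ransac", ransac_iterations = 100, seed = 1)
  m <- segment_ransac(r, NULL, cfg)
  expect_true(all(m$labels == MASK_GROUND))
})

test_that("RANSAC mask matches truth on >= 99% of pixels of a synthetic plot", {
  sc <- generate_orchard(extent = c(4.5, 4.5), gsd = 0.03, seed = 13,
                         point_density = 0, make_rgb = FALSE)
  cfg <- segmentation_config("ransac", ransac_iterations = 300, seed = 2)
  m <- segment_ransac(sc$dsm, NULL, cfg)
  expect_gte(mean(m$labels == sc$truth_mask$labels), 0.99)
})

test_that("plane fits stay consistent with truth across seeded scenes", {
  # the backend's working regime: canopy (outlier) fraction below 30% and
  # crowns at least twice the distance threshold above ground
  for (s in 1:20) {
    sc <- generate_orchard(extent = c(4.5, 4.5), gsd = 0.05, seed = 100 + s,
                           crown_radius = c(0.5, 0.65),
                           point_density = 0, make_rgb = FALSE)
    expect_lt(mean(sc$truth_mask$labels == MASK_CANOPY), 0.3)
    cfg <- segmentation_config("ransac", ransac_iterations = 1000, seed = s)
    m <- segment_ransac(sc$dsm, NULL, cfg)
    expect_gte(mean(m$labels == sc$truth_mask$labels), 0.99,
               label = sprintf("scene seed %d agreement", 100 + s))
  }
})

test_that("below-plane outliers are classified ground, not canopy", {
  set.seed(4)
  v <- matrix(10, 20, 20)
  v[1, 1:5] <- 5   # pits well below the plane
  v[20, 20] <- 10.5  # above plane beyond threshold
  m <- segment_ransac(elevation_raster(v, gsd = 0.25), NULL,
                      segmentation_config("ransac", ransac_iterations = 100,
                                          ransac_distance = 0.2, seed = 1))
  expect_true(all(m$labels[1, 1:5] == MASK_GROUND))
  expect_equal(m$labels[20, 20], MASK_CANOPY)
})

test_that("ground bumps above the distance threshold fool RANSAC but not Otsu", {
  # weed bumps of 0.3 m: above the 0.2 m RANSAC threshold, far below canopy
  set.seed(9)
  v <- matrix(rnorm(50 * 50, 0, 0.01), 50, 50)
  bump_px <- cbind(sample(1:25, 12), sample(1:50, 12))
  v[bump_px] <- v[bump_px] + 0.3
  canopy_px <- cbind(sample(26:50, 200, replace = TRUE),
                     sample(1:50, 200, replace = TRUE))
  canopy_px <- canopy_px[!duplicated(canopy_px), ]
  v[canopy_px] <- 3 + rnorm(nrow(canopy_px), 0, 0.2)
  r <- elevation_raster(v, gsd = 0.1)
  m_ransac <- segment_ransac(r, NULL,
                             segmentation_config("ransac",
                                                 ransac_iterations = 200,
                                                 seed = 1))
  m_otsu <- segment_otsu(r)
  expect_true(all(m_ransac$labels[bump_px] == MASK_CANOPY))
  expect_true(all(m_otsu$labels[bump_px] == MASK_GROUND))
})

test_that("all backends satisfy the shared window contract", {
  sc <- generate_orchard(extent = c(6, 6), gsd = 0.05, seed = 21,
                         point_density = 0, make_rgb = FALSE)
  v <- sc$dsm$values
  v[5:10, 5:10] <- NA
  r <- elevation_raster(v, sc$dsm$origin_x, sc$dsm$origin_y, sc$dsm$gsd)
  w <- partition_plots(r, 4.5)[1, ]
  for (backend in c("otsu", "ransac")) {
    cfg <- segmentation_config(backend, ransac_iterations = 100, seed = 3)
    m <- segment_plot(r, w, cfg)
    expect_s3_class(m, "class_mask")
    expect_equal(dim(m), c(w$row_stop - w$row_start, w$col_stop - w$col_start))
    # label completeness: valid pixels labeled, nodata conserved
    sub <- is.na(v[(w$row_start + 1):w$row_stop, (w$col_start + 1):w$col_stop])
    expect_true(all((m$labels == MASK_NODATA) == sub), label = backend)
    # window georeference offset
    expect_equal(m$origin_x, r$origin_x + w$col_start * r$gsd)
    expect_equal(m$origin_y, r$origin_y - w$row_start * r$gsd)
  }
  expect_error(segment_otsu(r, list(plot_i = 0, plot_j = 0, row_start = 3,
                                    row_stop = 3, col_start = 0,
                                    col_stop = 5)), "empty window")
})

test_that("segment_raster stitches per-plot masks into a full-extent mask", {
  sc <- generate_orchard(extent = c(9, 4.5), gsd = 0.05, seed = 8,
                         point_density = 0, make_rgb = FALSE)
  m <- segment_raster(sc$dsm, segmentation_config("otsu", seed = 1))
  expect_equal(dim(m), dim(sc$dsm))
  expect_true(all(m$labels != MASK_NODATA))
  expect_gte(mean(m$labels == sc$truth_mask$labels), 0.99)
})
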