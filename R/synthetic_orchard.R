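# Synthetic orchard scenes with analytically known ground truth.
#
# The generator emulates the survey geometry this toolkit targets: tree rows
# 4.5 m apart, trees 1.5 m apart along the row, ~4 m tall, on a gently
# sloping ground plane, rasterized to a DSM at 0.016 m/pixel. Canopy crowns
# are solids of revolution (upper surface only), because a photogrammetric
# DSM sees only the upper canopy surface; the scene's "true" per-plot volume
# is therefore the DSM-visible volume under the truth mask, which is exactly
# what the pixel-integration estimator can recover when segmentation is
# perfect.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

crown_surface_height <- function(r2, c, shape) {
  # height of the crown's upper surface above its base plane, at normalized
  # squared radius r2 = ((x-bx)/a)^2 + ((y-by)/b)^2 <= 1
  switch(shape,
         half_ellipsoid = c * sqrt(pmax(0, 1 - r2)),
         cone = c * (1 - sqrt(pmin(1, r2))),
         stop("unknown crown shape: ", shape))
}

#' Closed-form crown volume
#'
#' Volume of the solid between a crown's upper surface and its base plane:
#' `(2/3) pi a b c` for a half-ellipsoid, `(1/3) pi a b c` for a cone.
#' Used as the analytic reference in resolution-convergence checks.
#'
#' @param a,b Horizontal semi-axes (m).
#' @param c Crown height (m).
#' @param shape `"half_ellipsoid"` or `"cone"`.
#' @return Volume in cubic meters.
#' @export
crown_closed_volume <- function(a, b, c, shape = "half_ellipsoid") {
  switch(shape,
         half_ellipsoid = 2 / 3 * pi * a * b * c,
         cone = 1 / 3 * pi * a * b * c,
         stop("unknown crown shape: ", shape))
}

#' Lay out trees in rows
#'
#' Regular orchard layout: rows parallel to the y axis spaced `row_spacing`
#' apart in x, trees spaced `tree_spacing` along each row, inset by half a
#' spacing from the extent edges. Per-tree crown parameters are drawn
#' uniformly from the supplied ranges.
#'
#' @param extent Numeric length-2, scene size `(x, y)` in meters.
#' @param row_spacing,tree_spacing Row and in-row spacing (m); defaults
#'   match a pear-orchard planting of 4.5 m x 1.5 m.
#' @param trunk_height,crown_height,crown_radius Length-2 ranges (m) for
#'   uniform draws of the trunk height, crown height `c`, and crown
#'   semi-axes `a = b`. Defaults give total tree heights around 4 m.
#' @param shape Crown shape for all trees.
#' @return data.frame with one row per tree: `base_x`, `base_y`,
#'   `trunk_height`, `a`, `b`, `c`, `shape`.
#' @export
layout_trees <- function(extent, row_spacing = 4.5, tree_spacing = 1.5,
                         trunk_height = c(0.8, 1.2),
                         crown_height = c(2.6, 3.2),
                         crown_radius = c(0.8, 1.1),
                         shape = "half_ellipsoid") {
  xs <- seq(row_spacing / 2, extent[1] - row_spacing / 2 + 1e-9, by = row_spacing)
  ys <- seq(tree_spacing / 2, extent[2] - tree_spacing / 2 + 1e-9, by = tree_spacing)
  if (length(xs) < 1L || length(ys) < 1L)
    stop("extent too small for even one tree at the given spacings")
  g <- expand.grid(base_x = xs, base_y = ys)
  n <- nrow(g)
  radius <- runif(n, crown_radius[1], crown_radius[2])
  data.frame(
    tree_id = seq_len(n),
    base_x = g$base_x, base_y = g$base_y,
    trunk_height = runif(n, trunk_height[1], trunk_height[2]),
    a = radius,
    b = radius,
    c = runif(n, crown_height[1], crown_height[2]),
    shape = shape,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic orchard scene
#'
#' Builds a DSM, truth label mask, RGB image, tree table, ground-plane
#' model and exact per-plot canopy volumes for a synthetic orchard. The
#' DSM is `max(ground surface, crown upper surfaces)` sampled at pixel
#' centers; a pixel is labeled canopy iff a crown surface lies strictly
#' above the ground there. Ground is a global plane plus optional weed
#' bumps: on a random fraction of ground pixels, a zero-mean Gaussian
#' perturbation truncated at zero (weeds stick up, never dig down).
#'
#' Per-plot true volume is defined exactly as the pixel-integration
#' estimator computes it from a perfect mask: the sum over canopy pixels
#' of `gsd^2 * max(0, h_pix - mean ground altitude of the plot)`. With the
#' truth mask this makes segmentation the only end-to-end error source.
#'
#' @param extent Scene size `(x, y)` in meters.
#' @param trees Optional tree table as returned by [layout_trees]; if
#'   `NULL` one is generated from the spacing arguments. Use a 0-row
#'   data.frame for a treeless scene.
#' @param row_spacing,tree_spacing Orchard layout (m), see [layout_trees].
#' @param gsd Raster resolution in m/pixel (default 0.016, the survey GSD).
#' @param base_altitude Plane altitude at world origin (m).
#' @param ground_slope Length-2 gradient `(dz/dx, dz/dy)`; default a
#'   gentle 2 percent hillside.
#' @param weed_noise_sd SD (m) of the truncated Gaussian weed bumps.
#' @param weed_patch_fraction Fraction of ground pixels carrying a bump.
#' @param plot_side Plot edge (m) used for the true per-plot volumes.
#' @param point_density Crown-surface sampling density (points/m^2) for
#'   the bundled point cloud; 0 skips cloud generation.
#' @param make_rgb Generate the RGB orthomosaic band (flat textures plus
#'   noise; disable to save memory on large scenes).
#' @param treetop_erosion Optional cap (m) lowered onto crown apexes to
#'   mimic photogrammetric treetop underestimation; default 0 (off).
#' @param seed Integer RNG seed; identical seed and parameters give a
#'   bit-identical scene.
#' @param ... Passed to [layout_trees] (crown parameter ranges).
#' @return An object of class `orchard_scene`: list with `dsm`
#'   ([elevation_raster]), `truth_mask` ([class_mask]), `rgb` (list or
#'   `NULL`), `trees`, `ground_plane` ([plane_model]), `point_cloud`
#'   (n x 3 matrix or NULL), `true_volumes` (data.frame `plot_i`,
#'   `plot_j`, `volume`, `mean_ground_alt`), `plot_side`, `params`.
#' @examples
#' sc <- generate_orchard(extent = c(9, 4.5), gsd = 0.05, seed = 1,
#'                        point_density = 0, make_rgb = FALSE)
#' sc$true_volumes
#' @export
generate_orchard <- function(extent = c(22.5, 13.5),
                             trees = NULL,
                             row_spacing = 4.5, tree_spacing = 1.5,
                             gsd = 0.016,
                             base_altitude = 50,
                             ground_slope = c(0.02, 0.01),
                             weed_noise_sd = 0.05,
                             weed_patch_fraction = 0.2,
                             plot_side = 4.5,
                             point_density = 200,
                             make_rgb = TRUE,
                             treetop_erosion = 0,
                             seed = 1, ...) {
  if (weed_noise_sd < 0) stop("`weed_noise_sd` must be >= 0")
  if (gsd <= 0) stop("`gsd` must be positive")
  with_seed(seed, {
    nc <- max(1L, as.integer(round(extent[1] / gsd)))
    nr <- max(1L, as.integer(round(extent[2] / gsd)))
    origin_x <- 0; origin_y <- extent[2]
    xc <- origin_x + (seq_len(nc) - 0.5) * gsd
    yc <- origin_y - (seq_len(nr) - 0.5) * gsd

    if (is.null(trees))
      trees <- layout_trees(extent, row_spacing, tree_spacing, ...)

    # ground: global plane (+ truncated-Gaussian weed bumps)
    sx <- ground_slope[1]; sy <- ground_slope[2]
    ground <- base_altitude + outer(yc * sy, xc * sx, `+`)
    if (weed_noise_sd > 0 && weed_patch_fraction > 0) {
      weedy <- runif(nr * nc) < weed_patch_fraction
      bumps <- numeric(nr * nc)
      bumps[weedy] <- pmax(0, rnorm(sum(weedy), 0, weed_noise_sd))
      ground <- ground + matrix(bumps, nr, nc)
    }

    # crowns: max-combined upper surfaces
    crown <- matrix(-Inf, nr, nc)
    if (nrow(trees) > 0) for (k in seq_len(nrow(trees))) {
      tr <- trees[k, ]
      ci <- which(abs(xc - tr$base_x) <= tr$a)
      ri <- which(abs(yc - tr$base_y) <= tr$b)
      if (!length(ci) || !length(ri)) next
      r2 <- outer(((yc[ri] - tr$base_y) / tr$b)^2,
                  ((xc[ci] - tr$base_x) / tr$a)^2, `+`)
      inside <- r2 <= 1
      z0 <- base_altitude + sx * tr$base_x + sy * tr$base_y + tr$trunk_height
      surf <- z0 + crown_surface_height(r2, tr$c, tr$shape)
      if (treetop_erosion > 0)
        surf <- pmin(surf, z0 + tr$c - treetop_erosion)
      surf[!inside] <- -Inf
      crown[ri, ci] <- pmax(crown[ri, ci], surf)
    }

    canopy <- crown > ground
    dsm_values <- pmax(ground, crown)
    dsm <- elevation_raster(dsm_values, origin_x, origin_y, gsd)
    labels <- matrix(MASK_GROUND, nr, nc)
    labels[canopy] <- MASK_CANOPY
    truth_mask <- class_mask(labels, origin_x, origin_y, gsd)

    rgb <- NULL
    if (make_rgb) {
      mk <- function(g_can, g_gnd) {
        v <- matrix(g_gnd, nr, nc); v[canopy] <- g_can
        pmin(pmax(v + matrix(rnorm(nr * nc, 0, 0.03), nr, nc), 0), 1)
      }
      rgb <- list(rgb = array(c(mk(0.20, 0.45), mk(0.45, 0.35), mk(0.15, 0.22)),
                              c(nr, nc, 3)),
                  origin_x = origin_x, origin_y = origin_y, gsd = gsd)
    }

    L <- sqrt(sx^2 + sy^2 + 1)
    ground_plane <- plane_model(c(-sx, -sy, 1) / L, -base_altitude / L)

    scene <- structure(list(
      dsm = dsm, truth_mask = truth_mask, rgb = rgb, trees = trees,
      ground_plane = ground_plane, point_cloud = NULL,
      true_volumes = NULL, plot_side = plot_side,
      params = list(extent = extent, row_spacing = row_spacing,
                    tree_spacing = tree_spacing, gsd = gsd,
                    base_altitude = base_altitude, ground_slope = ground_slope,
                    weed_noise_sd = weed_noise_sd,
                    weed_patch_fraction = weed_patch_fraction,
                    plot_side = plot_side, point_density = point_density,
                    treetop_erosion = treetop_erosion, seed = seed)
    ), class = "orchard_scene")

    # exact per-plot truth via the package's own volume summation
    plots <- partition_plots(dsm, plot_side)
    tv <- measure_all(dsm, truth_mask, plots)
    scene$true_volumes <- tv[, c("plot_i", "plot_j", "volume", "mean_ground_alt")]

    if (point_density > 0)
      scene$point_cloud <- sample_point_cloud(scene, density = point_density,
                                              seed = seed + 1L)
    scene
  })
}

#' @export
print.orchard_scene <- function(x, ...) {
  d <- dim(x$dsm$values)
  cat(sprintf(
    "<orchard_scene> %d x %d px (gsd %g m), %d trees, %d plots, total true volume %.3f m^3\n",
    d[1], d[2], x$dsm$gsd, nrow(x$trees), nrow(x$true_volumes),
    sum(x$true_volumes$volume)))
  invisible(x)
}

#' Sample a canopy point cloud from a scene
#'
#' Emulates a ground-removed mobile laser scan of the crowns. In
#' `"surface"` mode points lie exactly on the crown upper surfaces
#' (rejection sampling, uniform per unit area), with expected count
#' `density` (points/m^2) times total crown surface area. In `"solid"`
#' mode points fill the crown solids uniformly with `density` in
#' points/m^3 — used when validating voxel-volume convergence, where a
#' surface-only cloud would leave interior voxels empty.
#'
#' @param scene An `orchard_scene`.
#' @param density Sampling density: points/m^2 (surface) or points/m^3
#'   (solid).
#' @param seed Integer RNG seed.
#' @param mode `"surface"` or `"solid"`.
#' @return Numeric matrix with columns `x`, `y`, `z` (m); 0-row for a
#'   treeless scene.
#' @export
sample_point_cloud <- function(scene, density = 200, seed = 1,
                               mode = c("surface", "solid")) {
  mode <- match.arg(mode)
  if (density <= 0) stop("`density` must be positive")
  trees <- scene$trees
  if (is.null(trees) || nrow(trees) == 0)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  sl <- scene$params$ground_slope
  base_alt <- scene$params$base_altitude
  with_seed(seed, {
    pts <- vector("list", nrow(trees))
    for (k in seq_len(nrow(trees))) {
      tr <- trees[k, ]
      z0 <- base_alt + sl[1] * tr$base_x + sl[2] * tr$base_y + tr$trunk_height
      pts[[k]] <- if (mode == "surface")
        sample_crown_surface(tr, z0, density)
      else
        sample_crown_solid(tr, z0, density)
    }
    out <- do.call(rbind, pts)
    colnames(out) <- c("x", "y", "z")
    out
  })
}

# Uniform-per-area sampling of a crown upper surface by rejection from the
# unit upper hemisphere: a point u there maps to (a ux, b uy, c uz); the
# area scale factor is sqrt((bc ux)^2 + (ac uy)^2 + (ab uz)^2).
sample_crown_surface <- function(tr, z0, density) {
  a <- tr$a; b <- tr$b; cc <- tr$c
  if (tr$shape == "half_ellipsoid") {
    smax <- max(b * cc, a * cc, a * b)
    n_prop <- max(1L, as.integer(round(density * 2 * pi * smax)))
    uz <- runif(n_prop)
    phi <- runif(n_prop, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - uz^2))
    ux <- s * cos(phi); uy <- s * sin(phi)
    sig <- sqrt((b * cc * ux)^2 + (a * cc * uy)^2 + (a * b * uz)^2)
    keep <- runif(n_prop) < sig / smax
    cbind(tr$base_x + a * ux[keep], tr$base_y + b * uy[keep],
          z0 + cc * uz[keep])
  } else if (tr$shape == "cone") {
    if (abs(a - b) > 1e-12)
      stop("cone surface sampling supports circular crowns (a == b) only")
    slant <- sqrt(a^2 + cc^2)
    area <- pi * a * slant
    n <- max(1L, as.integer(round(density * area)))
    r <- sqrt(runif(n))            # area element on a cone is prop. to r
    phi <- runif(n, 0, 2 * pi)
    cbind(tr$base_x + a * r * cos(phi), tr$base_y + a * r * sin(phi),
          z0 + cc * (1 - r))
  } else stop("unknown crown shape: ", tr$shape)
}

# Uniform sampling of the crown solid (between base plane and upper surface).
sample_crown_solid <- function(tr, z0, density) {
  a <- tr$a; b <- tr$b; cc <- tr$c
  vol <- crown_closed_volume(a, b, cc, tr$shape)
  n <- max(1L, as.integer(round(density * vol)))
  if (tr$shape == "half_ellipsoid") {
    g <- matrix(rnorm(3 * n), n, 3)
    g <- g / sqrt(rowSums(g^2))
    g[, 3] <- abs(g[, 3])
    u <- runif(n)^(1 / 3)
    cbind(tr$base_x + a * u * g[, 1], tr$base_y + b * u * g[, 2],
          z0 + cc * u * g[, 3])
  } else if (tr$shape == "cone") {
    # height fraction h has density prop. to (1-h)^2
    h <- 1 - (1 - runif(n))^(1 / 3)
    r <- sqrt(runif(n)) * (1 - h)
    phi <- runif(n, 0, 2 * pi)
    cbind(tr$base_x + a * r * cos(phi), tr$base_y + b * r * sin(phi),
          z0 + cc * h)
  } else stop("unknown crown shape: ", tr$shape)
}

#' Propose training tiles from disjoint scene regions
#'
#' Splits the scene into three disjoint vertical bands (training,
#' validation, test sampling regions, emulating separate subfields) and
#' draws random tile windows within each. Returns window specifications;
#' use [extract_tile] to materialize a tile's RGB+DSM channels and label
#' grid (the default counts would otherwise hold ~1.4 GB of pixels).
#'
#' @param scene An `orchard_scene` (with RGB).
#' @param tile_px Tile edge in pixels (default 281, i.e. 4.496 m at the
#'   survey GSD of 0.016 m/pixel).
#' @param n_train,n_val,n_test Number of tiles per split (defaults
#'   400/50/100).
#' @param region_fractions Column fractions of the three bands.
#' @param seed Integer RNG seed.
#' @return data.frame with columns `split`, `tile_id`, `row_start`,
#'   `row_stop`, `col_start`, `col_stop` (0-based half-open).
#' @export
make_training_tiles <- function(scene, tile_px = 281,
                                n_train = 400, n_val = 50, n_test = 100,
                                region_fractions = c(0.6, 0.15, 0.25),
                                seed = 1) {
  d <- dim(scene$dsm$values)
  if (tile_px > d[1]) stop("scene has fewer rows than one tile")
  edges <- round(cumsum(c(0, region_fractions / sum(region_fractions))) * d[2])
  splits <- c("train", "val", "test")
  counts <- c(n_train, n_val, n_test)
  with_seed(seed, {
    out <- vector("list", 3L)
    for (s in 1:3) {
      lo <- edges[s]; hi <- edges[s + 1]
      if (hi - lo < tile_px)
        stop("scene too small: the ", splits[s], " region is narrower (",
             hi - lo, " px) than one tile (", tile_px, " px)")
      n <- counts[s]
      rs <- sample.int(d[1] - tile_px + 1L, n, replace = TRUE) - 1L
      cs <- lo + sample.int(hi - lo - tile_px + 1L, n, replace = TRUE) - 1L
      out[[s]] <- data.frame(split = splits[s], tile_id = seq_len(n),
                             row_start = rs, row_stop = rs + tile_px,
                             col_start = cs, col_stop = cs + tile_px,
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
}

#' Materialize one training tile
#'
#' @param scene An `orchard_scene`.
#' @param tile One row of the data.frame from [make_training_tiles].
#' @return List with `dsm` (matrix), `rgb` (tile_px x tile_px x 3 array or
#'   `NULL`), `labels` (integer matrix) and `window`.
#' @export
extract_tile <- function(scene, tile) {
  w <- as.list(tile[1, c("row_start", "row_stop", "col_start", "col_stop")])
  rgb <- NULL
  if (!is.null(scene$rgb))
    rgb <- scene$rgb$rgb[(w$row_start + 1):w$row_stop,
                         (w$col_start + 1):w$col_stop, , drop = FALSE]
  list(dsm = window_values(scene$dsm, w), rgb = rgb,
       labels = window_labels(scene$truth_mask, w), window = w)
}

#' Write a scene to disk
#'
#' Writes `dsm.asc`, `truth_mask.png`, `rgb.tif` (if present),
#' `cloud.xyz` or `cloud.ply` (if present), `trees.csv`,
#' `truth_volumes.csv` and `scene.json` (all generation parameters
#' including the seed) into `dir`.
#'
#' @param scene An `orchard_scene`.
#' @param dir Output directory (created if missing).
#' @param cloud_format `"xyz"` or `"ply"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_scene <- function(scene, dir, cloud_format = c("xyz", "ply")) {
  cloud_format <- match.arg(cloud_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(f) file.path(dir, f)
  write_raster(scene$dsm, p("dsm.asc")); files <- c(files, p("dsm.asc"))
  write_mask(scene$truth_mask, p("truth_mask.png"))
  files <- c(files, p("truth_mask.png"))
  if (!is.null(scene$rgb)) {
    write_raster(scene$rgb, p("rgb.tif")); files <- c(files, p("rgb.tif"))
  }
  if (!is.null(scene$point_cloud) && nrow(scene$point_cloud) > 0) {
    f <- p(paste0("cloud.", cloud_format))
    write_point_cloud(scene$point_cloud, f); files <- c(files, f)
  }
  write.csv(scene$trees, p("trees.csv"), row.names = FALSE)
  write.csv(scene$true_volumes, p("truth_volumes.csv"), row.names = FALSE)
  jsonlite::write_json(scene$params, p("scene.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, p("trees.csv"), p("truth_volumes.csv"), p("scene.json"))
  invisible(files)
}
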