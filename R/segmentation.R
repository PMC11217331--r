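# Per-plot ground/canopy segmentation of an elevation raster.
#
# Two classical backends share one contract (raster + window -> class mask):
#   * otsu   — elevation-histogram thresholding maximizing between-class
#              variance; pixels above the threshold are canopy
#   * ransac — robust ground-plane fit; pixels more than the distance
#              threshold above the plane are canopy
# Plots are segmented independently: within one 4.5 m plot the ground is
# assumed planar even when the whole orchard sits on a hillside.

cond_error <- function(class, msg, call. = FALSE) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = if (call.) sys.call(-1))))
}

#' Segmentation configuration
#'
#' Bundles backend choice and parameters. Defaults are the survey
#' settings: 4.5 m plots; RANSAC with 50 sampling points, 10,000
#' iterations and a 0.2 m distance threshold; a 256-bin elevation
#' histogram for Otsu.
#'
#' @param backend `"otsu"` or `"ransac"`.
#' @param plot_side Plot edge length (m).
#' @param ransac_n_samples Points drawn per RANSAC iteration.
#' @param ransac_iterations RANSAC iteration count.
#' @param ransac_distance RANSAC inlier distance threshold (m); also the
#'   height above the fitted plane beyond which a pixel is canopy.
#' @param otsu_bins Histogram bin count for Otsu thresholding.
#' @param ground_roughness_floor Expected elevation roughness (m) of bare
#'   ground; plots whose elevation range is below twice this value are
#'   treated as treeless and labeled all ground (Otsu would otherwise
#'   threshold pure noise).
#' @param morphological_filter Placeholder hook; masks are deliberately
#'   not post-filtered by default, so segmentation differences propagate
#'   unaltered into the volumes. Must be `FALSE`.
#' @param seed Integer seed; per-plot RANSAC seeds are derived from it.
#' @return List of class `segmentation_config`.
#' @export
segmentation_config <- function(backend = c("otsu", "ransac"),
                                plot_side = 4.5,
                                ransac_n_samples = 50L,
                                ransac_iterations = 10000L,
                                ransac_distance = 0.2,
                                otsu_bins = 256L,
                                ground_roughness_floor = 0.1,
                                morphological_filter = FALSE,
                                seed = 1L) {
  backend <- match.arg(backend)
  if (ransac_distance <= 0) stop("`ransac_distance` must be positive")
  if (otsu_bins < 2) stop("`otsu_bins` must be at least 2")
  if (!identical(morphological_filter, FALSE))
    stop("mask post-filtering is not implemented; masks are used raw")
  structure(list(backend = backend, plot_side = plot_side,
                 ransac_n_samples = as.integer(ransac_n_samples),
                 ransac_iterations = as.integer(ransac_iterations),
                 ransac_distance = ransac_distance,
                 otsu_bins = as.integer(otsu_bins),
                 ground_roughness_floor = ground_roughness_floor,
                 seed = as.integer(seed)),
            class = "segmentation_config")
}

# ---- Otsu ------------------------------------------------------------------

#' Otsu threshold of an elevation sample
#'
#' Bins the elevations into an equal-width histogram and returns the bin
#' edge maximizing the between-class variance
#' `sigma_b^2(t) = w0 w1 (mu0 - mu1)^2`, where class 0 holds the bins at
#' or below the edge. Ground elevations cluster low and canopy elevations
#' high, so the maximizing edge falls between the two histogram peaks.
#' Ties are broken toward the lowest qualifying threshold.
#'
#' @param values Numeric vector of elevations (m); `NA` ignored.
#' @param bins Histogram bin count (default 256).
#' @return The threshold, in meters.
#' @examples
#' otsu_threshold(c(rep(0, 50), rep(10, 50)))
#' @export
otsu_threshold <- function(values, bins = 256L) {
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2L)
    cond_error("canovol_degenerate_histogram",
               "Otsu thresholding needs at least 2 distinct finite values")
  bins <- as.integer(bins)
  edges <- seq(min(v), max(v), length.out = bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  mids <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  n <- length(v)
  w0 <- cumsum(counts)[-bins] / n            # class 0 = bins 1..k
  w1 <- 1 - w0
  csum <- cumsum(counts * mids)
  mu0 <- csum[-bins] / pmax(cumsum(counts)[-bins], 1L)
  mu1 <- (csum[bins] - csum[-bins]) / pmax(n - cumsum(counts)[-bins], 1L)
  sigma_b2 <- w0 * w1 * (mu0 - mu1)^2
  sigma_b2[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(sigma_b2)                   # first max = lowest threshold
  edges[k + 1L]
}

window_georef <- function(raster, window) {
  list(origin_x = raster$origin_x + window$col_start * raster$gsd,
       origin_y = raster$origin_y - window$row_start * raster$gsd,
       gsd = raster$gsd)
}

full_window <- function(raster) {
  d <- dim(raster$values)
  list(plot_i = 0L, plot_j = 0L, row_start = 0L, row_stop = d[1],
       col_start = 0L, col_stop = d[2])
}

check_window <- function(raster, window) {
  d <- dim(raster$values)
  if (window$row_stop <= window$row_start ||
      window$col_stop <= window$col_start)
    stop("empty window")
  if (window$row_start < 0 || window$col_start < 0 ||
      window$row_stop > d[1] || window$col_stop > d[2])
    stop("window exceeds raster bounds")
}

#' Segment one plot by Otsu elevation thresholding
#'
#' Thresholds the plot's elevation histogram with [otsu_threshold];
#' pixels with elevation strictly above the threshold become canopy, the
#' rest ground. Nodata pixels are propagated. Near-flat plots (elevation
#' range below twice `ground_roughness_floor`) are labeled all ground:
#' a treeless plot has no bimodal histogram, only surface roughness.
#'
#' @param raster An [elevation_raster].
#' @param window A plot window (one row of [partition_plots] output, or
#'   `NULL` for the full raster).
#' @param config A [segmentation_config].
#' @return A [class_mask] covering the window extent.
#' @export
segment_otsu <- function(raster, window = NULL, config = segmentation_config()) {
  if (is.null(window)) window <- full_window(raster)
  check_window(raster, window)
  v <- window_values(raster, window)
  valid <- !is.na(v)
  labels <- matrix(MASK_NODATA, nrow(v), ncol(v))
  g <- window_georef(raster, window)
  if (sum(valid) == 0L)
    return(class_mask(labels, g$origin_x, g$origin_y, g$gsd))
  rng <- range(v[valid])
  if (length(unique(v[valid])) < 2L ||
      (rng[2] - rng[1]) < 2 * config$ground_roughness_floor) {
    labels[valid] <- MASK_GROUND
  } else {
    t <- otsu_threshold(v[valid], config$otsu_bins)
    labels[valid] <- ifelse(v[valid] > t, MASK_CANOPY, MASK_GROUND)
  }
  class_mask(labels, g$origin_x, g$origin_y, g$gsd)
}

# ---- RANSAC ----------------------------------------------------------------

#' Construct a plane model
#'
#' A plane `n . p + d = 0` with unit normal in canonical (upward)
#' orientation, so the signed residual `n . p + d` is positive above the
#' plane.
#'
#' @param normal Length-3 normal vector (normalized internally).
#' @param offset Scalar `d`.
#' @param inlier_count Number of inliers supporting the fit.
#' @param inliers Optional logical vector marking the inlier points.
#' @return Object of class `plane_model`.
#' @export
plane_model <- function(normal, offset, inlier_count = NA_integer_,
                        inliers = NULL) {
  nrm <- sqrt(sum(normal^2))
  if (nrm == 0) stop("degenerate plane normal")
  normal <- normal / nrm
  offset <- offset / nrm
  if (normal[3] < 0) { normal <- -normal; offset <- -offset }
  structure(list(normal = normal, offset = offset,
                 inlier_count = as.integer(inlier_count), inliers = inliers),
            class = "plane_model")
}

#' @export
print.plane_model <- function(x, ...) {
  cat(sprintf("<plane_model> normal (%.4f, %.4f, %.4f), offset %.4f, %s inliers\n",
              x$normal[1], x$normal[2], x$normal[3], x$offset,
              ifelse(is.na(x$inlier_count), "?", x$inlier_count)))
  invisible(x)
}

#' Signed height of points above a plane
#'
#' @param plane A [plane_model].
#' @param points n x 3 matrix.
#' @return Numeric vector `n . p + d` (positive above the plane).
#' @export
plane_residuals <- function(plane, points) {
  as.vector(points %*% plane$normal + plane$offset)
}

#' Fit a plane by RANSAC
#'
#' Repeatedly draws `n_samples` points, fits their least-squares plane,
#' and keeps the candidate with the most points within `distance` of it;
#' the winning model is refit by least squares on its inliers. Sampling
#' uses R's RNG, so results are reproducible under a seed.
#'
#' @param points n x 3 matrix of `(x, y, z)` coordinates (m).
#' @param n_samples Points per candidate fit (default 50).
#' @param iterations Number of candidates (default 10,000).
#' @param distance Inlier distance threshold in meters (default 0.2).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A [plane_model] with `inlier_count` and an `inliers` logical
#'   vector.
#' @examples
#' pts <- cbind(runif(100), runif(100), 0)
#' fit_plane_ransac(pts, iterations = 10, seed = 1)
#' @export
fit_plane_ransac <- function(points, n_samples = 50L, iterations = 10000L,
                             distance = 0.2, seed = NULL) {
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("`points` must be an n x 3 matrix")
  if (nrow(points) < 3L)
    cond_error("canovol_fit_failure", "plane fitting needs at least 3 points")
  run <- function() .ransac_plane_cpp(points, as.integer(n_samples),
                                      as.integer(iterations), distance)
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  if (!isTRUE(res$ok))
    cond_error("canovol_fit_failure",
               "no valid plane candidate found (points collinear?)")
  plane_model(res$normal, res$offset, sum(res$inliers), res$inliers)
}

#' Segment one plot by RANSAC ground-plane fitting
#'
#' Converts the plot's valid pixels to `(x, y, z)` points at pixel
#' centers, fits the ground plane by RANSAC, and labels canopy every
#' pixel whose signed height above the plane exceeds the distance
#' threshold. Plane inliers and below-plane outliers are ground (canopy
#' is physically above ground). If the fit fails the window is labeled
#' nodata with a warning.
#'
#' @inheritParams segment_otsu
#' @param seed Seed for the RANSAC draw; defaults to `config$seed`.
#' @return A [class_mask] covering the window extent.
#' @export
segment_ransac <- function(raster, window = NULL,
                           config = segmentation_config("ransac"),
                           seed = config$seed) {
  if (is.null(window)) window <- full_window(raster)
  check_window(raster, window)
  v <- window_values(raster, window)
  valid <- !is.na(v)
  labels <- matrix(MASK_NODATA, nrow(v), ncol(v))
  g <- window_georef(raster, window)
  if (sum(valid) >= 3L) {
    ctr <- window_centers(raster, window)
    pts <- cbind(ctr$x[valid], ctr$y[valid], v[valid])
    fit <- tryCatch(
      fit_plane_ransac(pts, config$ransac_n_samples, config$ransac_iterations,
                       config$ransac_distance, seed = seed),
      canovol_fit_failure = function(e) NULL)
    if (is.null(fit)) {
      warning("RANSAC plane fit failed for plot (", window$plot_i, ", ",
              window$plot_j, "); window labeled nodata")
    } else {
      h <- plane_residuals(fit, pts)
      labels[valid] <- ifelse(h > config$ransac_distance,
                              MASK_CANOPY, MASK_GROUND)
    }
  }
  class_mask(labels, g$origin_x, g$origin_y, g$gsd)
}

# ---- common driver ---------------------------------------------------------

#' Segment one plot with the configured backend
#'
#' All backends share this contract: an elevation raster plus a plot
#' window in, a window-extent class mask out, every valid pixel labeled
#' and nodata conserved.
#'
#' @inheritParams segment_otsu
#' @param seed Per-plot seed for stochastic backends.
#' @return A [class_mask].
#' @export
segment_plot <- function(raster, window = NULL,
                         config = segmentation_config(), seed = config$seed) {
  switch(config$backend,
         otsu = segment_otsu(raster, window, config),
         ransac = segment_ransac(raster, window, config, seed = seed),
         stop("unknown backend: ", config$backend))
}

#' Segment a whole raster plot by plot
#'
#' Partitions the raster into `config$plot_side` plots, segments each
#' independently with the configured backend, and stitches the per-plot
#' masks into one full-extent mask. Per-plot RANSAC seeds are derived
#' from `config$seed` plus the plot's row-major index, so any plot can be
#' re-segmented in isolation reproducibly.
#'
#' @param raster An [elevation_raster].
#' @param config A [segmentation_config].
#' @param plots Optional precomputed [partition_plots] data.frame.
#' @return A [class_mask] with the raster's full extent.
#' @export
segment_raster <- function(raster, config = segmentation_config(),
                           plots = NULL) {
  if (is.null(plots)) plots <- partition_plots(raster, config$plot_side)
  d <- dim(raster$values)
  labels <- matrix(MASK_NODATA, d[1], d[2])
  for (k in seq_len(nrow(plots))) {
    w <- plots[k, ]
    m <- segment_plot(raster, w, config, seed = config$seed + k)
    labels[(w$row_start + 1):w$row_stop,
           (w$col_start + 1):w$col_stop] <- m$labels
  }
  class_mask(labels, raster$origin_x, raster$origin_y, raster$gsd)
}
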