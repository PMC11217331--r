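# Per-plot canopy volume and tree-height extraction.
#
# Canopy volume of a plot is the pixel integration
#     V = sum over canopy pixels of gsd^2 * (h_pix - h_ground)
# where h_ground is the mean altitude of the plot's ground-labeled pixels.
# This is a canopy height model integral that needs no terrain model: the
# per-plot ground mean stands in for the DTM under the plot-planarity
# assumption.

#' Mean ground altitude of a plot
#'
#' Arithmetic mean of the raster values at ground-labeled pixels inside
#' the window.
#'
#' @param raster An [elevation_raster].
#' @param mask A [class_mask] aligned to `raster` (full extent).
#' @param window Plot window (`NULL` for the full raster).
#' @return Altitude in meters.
#' @export
mean_ground_altitude <- function(raster, mask, window = NULL) {
  if (is.null(window)) window <- full_window(raster)
  v <- window_values(raster, window)
  lab <- window_labels(mask, window)
  g <- lab == MASK_GROUND & !is.na(v)
  if (!any(g))
    cond_error("canovol_no_ground",
               sprintf("no ground pixels in plot (%s, %s)",
                       window$plot_i, window$plot_j))
  mean(v[g])
}

#' Canopy volume of one plot
#'
#' Sums, over the window's canopy pixels, the pixel footprint area
#' `gsd^2` times the pixel's height above the plot's mean ground
#' altitude. Nodata pixels contribute nothing. By default, canopy pixels
#' lying below the ground mean (possible under misclassification) are
#' clamped to zero height so a volume can never go negative; set
#' `clamp_negative = FALSE` for the strict unclamped sum.
#'
#' @param raster An [elevation_raster].
#' @param mask A [class_mask] aligned to `raster`.
#' @param window Plot window (`NULL` for the full raster).
#' @param mean_ground_alt Plot ground altitude (m); computed from the
#'   mask via [mean_ground_altitude] when omitted.
#' @param clamp_negative Clamp negative per-pixel heights to zero.
#' @return A one-row data.frame: `plot_i`, `plot_j`, `volume` (m^3),
#'   `mean_ground_alt` (m), `n_canopy_px`, `n_ground_px`.
#' @examples
#' r <- elevation_raster(matrix(2, 10, 10), gsd = 0.016)
#' m <- class_mask(matrix(MASK_CANOPY, 10, 10), gsd = 0.016)
#' canopy_volume(r, m, mean_ground_alt = 0)$volume  # 100 * 0.016^2 * 2
#' @export
canopy_volume <- function(raster, mask, window = NULL, mean_ground_alt = NULL,
                          clamp_negative = TRUE) {
  if (is.null(window)) window <- full_window(raster)
  if (is.null(mean_ground_alt))
    mean_ground_alt <- mean_ground_altitude(raster, mask, window)
  if (!is.finite(mean_ground_alt)) stop("`mean_ground_alt` must be finite")
  v <- window_values(raster, window)
  lab <- window_labels(mask, window)
  can <- lab == MASK_CANOPY & !is.na(v)
  h <- v[can] - mean_ground_alt
  if (clamp_negative) h <- pmax(0, h)
  data.frame(plot_i = window$plot_i, plot_j = window$plot_j,
             volume = raster$gsd^2 * sum(h),
             mean_ground_alt = mean_ground_alt,
             n_canopy_px = sum(can),
             n_ground_px = sum(lab == MASK_GROUND & !is.na(v)))
}

#' Tree height around a surveyed base position
#'
#' Collects the surface samples within `radius` meters (horizontal
#' Euclidean distance) of the tree base and returns the difference
#' between their maximum and minimum heights. Works on an
#' [elevation_raster] (pixels whose centers fall in the disc; at the
#' survey resolution the 0.25 m default radius spans about 15.6 pixels)
#' or on an n x 3 point-cloud matrix.
#'
#' @param surface An [elevation_raster] or n x 3 matrix of `(x, y, z)`.
#' @param base_x,base_y Tree base coordinates (m, same CRS as the surface).
#' @param radius Search radius in meters (default 0.25).
#' @return Height in meters.
#' @export
tree_height <- function(surface, base_x, base_y, radius = 0.25) {
  if (inherits(surface, "elevation_raster")) {
    d <- dim(surface$values)
    gsd <- surface$gsd
    # candidate pixel band, then exact point-in-disc test on centers
    cols <- which(abs(surface$origin_x + (seq_len(d[2]) - 0.5) * gsd - base_x)
                  <= radius)
    rows <- which(abs(surface$origin_y - (seq_len(d[1]) - 0.5) * gsd - base_y)
                  <= radius)
    if (!length(cols) || !length(rows))
      cond_error("canovol_insufficient_support",
                 "fewer than 2 surface samples within the search radius")
    xc <- surface$origin_x + (cols - 0.5) * gsd
    yc <- surface$origin_y - (rows - 0.5) * gsd
    d2 <- outer((yc - base_y)^2, (xc - base_x)^2, `+`)
    z <- surface$values[rows, cols, drop = FALSE][d2 <= radius^2]
    z <- z[!is.na(z)]
  } else {
    p <- as.matrix(surface)
    sel <- (p[, 1] - base_x)^2 + (p[, 2] - base_y)^2 <= radius^2
    z <- p[sel, 3]
  }
  if (length(z) < 2L)
    cond_error("canovol_insufficient_support",
               "fewer than 2 surface samples within the search radius")
  max(z) - min(z)
}

#' Tree heights for a table of surveyed bases
#'
#' @param surface An [elevation_raster] or n x 3 point matrix.
#' @param trees data.frame with columns `base_x`, `base_y` (and optionally
#'   `tree_id`).
#' @param radius Search radius (m).
#' @return data.frame `tree_id`, `base_x`, `base_y`, `height` (m; `NA`
#'   where the disc held fewer than 2 samples), `source` (`"dsm"` or
#'   `"point_cloud"`).
#' @export
tree_heights <- function(surface, trees, radius = 0.25) {
  src <- if (inherits(surface, "elevation_raster")) "dsm" else "point_cloud"
  ids <- if ("tree_id" %in% names(trees)) trees$tree_id else seq_len(nrow(trees))
  h <- vapply(seq_len(nrow(trees)), function(i) {
    tryCatch(tree_height(surface, trees$base_x[i], trees$base_y[i], radius),
             canovol_insufficient_support = function(e) NA_real_)
  }, numeric(1))
  data.frame(tree_id = ids, base_x = trees$base_x, base_y = trees$base_y,
             height = h, source = src, stringsAsFactors = FALSE)
}

#' Measure canopy volume for every plot
#'
#' Batch driver: computes one [canopy_volume] row per plot window.
#' Per-plot failures (e.g. a fully canopy-covered plot with no ground
#' pixels) never abort the batch; the plot's volume is `NA` and the
#' failure is recorded in the `error` column. With
#' `neighbor_fallback = TRUE`, plots without ground pixels borrow the
#' mean ground altitude of their (up to 8) neighboring plots.
#'
#' @param raster An [elevation_raster].
#' @param mask A full-extent [class_mask] aligned to `raster`.
#' @param plots [partition_plots] data.frame.
#' @param trees Optional tree table; heights are attached as the
#'   `"trees"` attribute (see [tree_heights]).
#' @param radius Tree-height search radius (m).
#' @param clamp_negative See [canopy_volume].
#' @param neighbor_fallback Use neighboring plots' ground means for
#'   plots lacking ground pixels.
#' @return data.frame with the [canopy_volume] columns plus `error`
#'   (`NA` or a message).
#' @export
measure_all <- function(raster, mask, plots, trees = NULL, radius = 0.25,
                        clamp_negative = TRUE, neighbor_fallback = FALSE) {
  rows <- vector("list", nrow(plots))
  for (k in seq_len(nrow(plots))) {
    w <- plots[k, ]
    rows[[k]] <- tryCatch({
      pv <- canopy_volume(raster, mask, w, clamp_negative = clamp_negative)
      pv$error <- NA_character_
      pv
    }, error = function(e) {
      data.frame(plot_i = w$plot_i, plot_j = w$plot_j, volume = NA_real_,
                 mean_ground_alt = NA_real_, n_canopy_px = NA_integer_,
                 n_ground_px = NA_integer_, error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  if (neighbor_fallback && any(is.na(out$volume))) {
    for (k in which(is.na(out$volume))) {
      nb <- abs(out$plot_i - out$plot_i[k]) <= 1 &
            abs(out$plot_j - out$plot_j[k]) <= 1 &
            !(out$plot_i == out$plot_i[k] & out$plot_j == out$plot_j[k])
      galt <- out$mean_ground_alt[nb]
      galt <- galt[is.finite(galt)]
      if (length(galt)) {
        pv <- canopy_volume(raster, mask, plots[k, ],
                            mean_ground_alt = mean(galt),
                            clamp_negative = clamp_negative)
        out[k, names(pv)] <- pv
        out$error[k] <- "ground mean borrowed from neighboring plots"
      }
    }
  }
  if (!is.null(trees))
    attr(out, "trees") <- tree_heights(raster, trees, radius)
  out
}
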