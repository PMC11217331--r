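# Georeferenced single-band rasters, class masks, and plot partitioning.
#
# Conventions (documented once, used everywhere):
#   * pixel indices are 0-based; windows are half-open [start, stop)
#   * row 0 is the northernmost row (north-up raster)
#   * (origin_x, origin_y) is the world coordinate of the upper-left corner
#     of pixel (0, 0); the center of pixel (r, c) is at
#     x = origin_x + (c + 0.5) * gsd,  y = origin_y - (r + 0.5) * gsd
#   * all world units are meters (projected / local CRS)

#' Construct an elevation raster
#'
#' An elevation raster is a georeferenced single-band grid of surface
#' altitudes (a DSM when it includes vegetation). Missing cells are `NA`
#' in `values`; the nodata mask is derived from them.
#'
#' @param values Numeric matrix of altitudes in meters; row 1 is the
#'   northernmost row. `NA` marks nodata cells.
#' @param origin_x,origin_y World coordinates (m) of the upper-left corner
#'   of the upper-left pixel.
#' @param gsd Ground sample distance: pixel edge length in m/pixel
#'   (square pixels).
#' @return An object of class `elevation_raster` with fields `values`,
#'   `origin_x`, `origin_y`, `gsd`.
#' @examples
#' r <- elevation_raster(matrix(5, 10, 10), gsd = 0.5)
#' dim(r)
#' @export
elevation_raster <- function(values, origin_x = 0, origin_y = nrow(values) * gsd,
                             gsd = 1) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(gsd) || length(gsd) != 1L || !is.finite(gsd) || gsd <= 0)
    stop("`gsd` must be a single positive number (m/pixel)")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("raster must have at least one row and one column")
  if (any(is.infinite(values)))
    stop("raster values must be finite or NA")
  structure(
    list(values = values, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), gsd = as.numeric(gsd)),
    class = "elevation_raster"
  )
}

#' @export
dim.elevation_raster <- function(x) dim(x$values)

#' @export
print.elevation_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<elevation_raster> %d x %d px, gsd %g m/px, origin (%g, %g), %d nodata\n",
    d[1], d[2], x$gsd, x$origin_x, x$origin_y, sum(is.na(x$values))))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  altitude range: [%g, %g] m\n", rng[1], rng[2]))
  invisible(x)
}

#' Nodata mask of a raster
#'
#' @param raster An [elevation_raster].
#' @return Logical matrix, `TRUE` where the cell holds no data.
#' @export
nodata_mask <- function(raster) is.na(raster$values)

#' Construct a class mask
#'
#' A class mask assigns each pixel of a paired raster one of the labels
#' ground (1), canopy (2) or nodata (0); see [mask-codes]. It shares the
#' raster's shape and georeference.
#'
#' @param labels Integer matrix over `{0, 1, 2}`.
#' @param origin_x,origin_y,gsd Georeference, as in [elevation_raster].
#' @param raster Optional [elevation_raster] supplying the georeference
#'   (and, with `strict = TRUE`, a shape/nodata consistency check).
#' @param strict If `TRUE` and `raster` is given, error unless shapes match
#'   and the mask is nodata exactly where the raster is.
#' @return An object of class `class_mask`.
#' @export
class_mask <- function(labels, origin_x = 0, origin_y = nrow(labels) * gsd,
                       gsd = 1, raster = NULL, strict = FALSE) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% c(MASK_NODATA, MASK_GROUND, MASK_CANOPY)))
    stop("mask labels must be 0 (nodata), 1 (ground) or 2 (canopy)")
  if (!is.null(raster)) {
    origin_x <- raster$origin_x; origin_y <- raster$origin_y; gsd <- raster$gsd
    if (strict) {
      if (!identical(dim(labels), dim(raster$values)))
        stop("mask shape does not match raster shape")
      if (!identical(unname(labels == MASK_NODATA), unname(is.na(raster$values))))
        stop("mask NODATA cells do not coincide with raster nodata cells")
    }
  }
  structure(
    list(labels = labels, origin_x = as.numeric(origin_x),
         origin_y = as.numeric(origin_y), gsd = as.numeric(gsd)),
    class = "class_mask"
  )
}

#' @export
dim.class_mask <- function(x) dim(x$labels)

#' @export
print.class_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<class_mask> %d x %d px: %d ground, %d canopy, %d nodata\n",
              d[1], d[2], sum(x$labels == MASK_GROUND),
              sum(x$labels == MASK_CANOPY), sum(x$labels == MASK_NODATA)))
  invisible(x)
}

# ---- file formats ----------------------------------------------------------

raster_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("asc", "agr", "grd")) return("asc")
  if (ext %in% c("tif", "tiff")) return("tif")
  if (ext == "png") return("png")
  stop("unsupported raster file extension: .", ext,
       " (supported: .asc, .tif, .png)")
}

world_file_path <- function(path) {
  ext <- tolower(tools::file_ext(path))
  sub(paste0("\\.", ext, "$"), switch(ext, tif = ".tfw", tiff = ".tfw",
                                      png = ".pgw", ".wld"),
      path, ignore.case = TRUE)
}

# ESRI world file: pixel size, rotation terms, center of upper-left pixel.
write_world_file <- function(path, origin_x, origin_y, gsd) {
  lines <- sprintf("%.17g",
                   c(gsd, 0, 0, -gsd, origin_x + gsd / 2, origin_y - gsd / 2))
  writeLines(lines, world_file_path(path))
}

read_world_file <- function(path) {
  wf <- world_file_path(path)
  if (!file.exists(wf)) return(NULL)
  v <- as.numeric(readLines(wf, n = 6))
  if (length(v) != 6 || any(!is.finite(v))) stop("malformed world file: ", wf)
  if (v[2] != 0 || v[3] != 0) stop("rotated rasters are not supported: ", wf)
  if (abs(v[1]) != abs(v[4]))
    stop("non-square pixels (|x size| != |y size|) in ", wf)
  list(gsd = abs(v[1]), origin_x = v[5] - abs(v[1]) / 2,
       origin_y = v[6] + abs(v[1]) / 2)
}

DEFAULT_NODATA <- -9999

guard_degree_crs <- function(gsd, meters_per_unit, path) {
  # A projected CRS in meters has pixel sizes ~1e-3..1e2; geographic degrees
  # give ~1e-7..1e-5. Refuse degree-scale pixels unless a scale is supplied.
  if (is.null(meters_per_unit)) {
    if (gsd < 1e-4)
      stop("pixel size ", gsd, " in ", path, " looks like geographic degrees; ",
           "this tool requires linear meters. Pass `meters_per_unit` ",
           "(e.g. 111320 for degrees at the equator) to override.")
    1
  } else {
    as.numeric(meters_per_unit)
  }
}

#' Read a georeferenced raster
#'
#' Supported formats: ESRI ASCII grid (`.asc`; georeference in the header,
#' values stored as exact decimal text) and TIFF/PNG with an ESRI world
#' file sidecar (`.tfw` / `.pgw`). TIFF/PNG store 8-bit data and are used
#' for RGB orthomosaics and masks; elevation data should use `.asc`.
#'
#' @param path File to read.
#' @param band `"first"` returns an [elevation_raster] from the first band;
#'   `"rgb"` returns a list with a `h x w x 3` array `rgb` (values 0-1) plus
#'   the georeference.
#' @param meters_per_unit Override for rasters georeferenced in non-meter
#'   linear units; pixel sizes are multiplied by it. Degree-scale pixel
#'   sizes are refused unless this is supplied.
#' @return An [elevation_raster], or a list for `band = "rgb"`.
#' @export
read_raster <- function(path, band = c("first", "rgb"), meters_per_unit = NULL) {
  band <- match.arg(band)
  if (!file.exists(path)) stop("file not found: ", path)
  fmt <- raster_format(path)

  if (fmt == "asc") {
    if (band == "rgb") stop("ASCII grids are single-band; cannot read RGB")
    return(read_ascii_grid(path, meters_per_unit))
  }

  img <- if (fmt == "tif") tiff::readTIFF(path) else png::readPNG(path)
  wf <- read_world_file(path)
  if (is.null(wf))
    stop("no world file found for ", path,
         " (expected ", world_file_path(path), ")")
  scale <- guard_degree_crs(wf$gsd, meters_per_unit, path)
  gsd <- wf$gsd * scale

  if (band == "rgb") {
    if (length(dim(img)) < 3L || dim(img)[3] < 3L)
      stop("raster has fewer than 3 bands; cannot read RGB: ", path)
    return(list(rgb = img[, , 1:3, drop = FALSE], origin_x = wf$origin_x * scale,
                origin_y = wf$origin_y * scale, gsd = gsd))
  }
  if (length(dim(img)) == 3L) img <- img[, , 1]
  elevation_raster(img, origin_x = wf$origin_x * scale,
                   origin_y = wf$origin_y * scale, gsd = gsd)
}

read_ascii_grid <- function(path, meters_per_unit = NULL) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "[[:space:]]+")
  keys <- tolower(vapply(kv, `[`, "", 1))
  vals <- as.numeric(vapply(kv, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else DEFAULT_NODATA
  n_hdr <- sum(keys %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                           "xllcenter", "yllcenter", "cellsize", "nodata_value"))
  scale <- guard_degree_crs(vals[["cellsize"]], meters_per_unit, path)
  gsd <- vals[["cellsize"]] * scale

  v <- scan(path, what = double(), skip = n_hdr, quiet = TRUE)
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  if (length(v) != nr * nc)
    stop("ASCII grid data size mismatch in ", path)
  m <- matrix(v, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  xll <- if ("xllcorner" %in% keys) vals[["xllcorner"]]
         else vals[["xllcenter"]] - vals[["cellsize"]] / 2
  yll <- if ("yllcorner" %in% keys) vals[["yllcorner"]]
         else vals[["yllcenter"]] - vals[["cellsize"]] / 2
  elevation_raster(m, origin_x = xll * scale,
                   origin_y = (yll + nr * vals[["cellsize"]]) * scale, gsd = gsd)
}

#' Write a georeferenced raster
#'
#' Elevation rasters are written as ESRI ASCII grids (`.asc`), which
#' round-trip double-precision values exactly. RGB arrays are written as
#' 8-bit TIFF/PNG with a world-file sidecar.
#'
#' @param raster An [elevation_raster], or for RGB output a list with
#'   fields `rgb` (h x w x 3 array, 0-1), `origin_x`, `origin_y`, `gsd`.
#' @param path Output file (`.asc` for elevation; `.tif`/`.png` for RGB).
#' @param nodata Nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, nodata = DEFAULT_NODATA) {
  fmt <- raster_format(path)
  if (inherits(raster, "elevation_raster")) {
    if (fmt != "asc")
      stop("elevation rasters are stored as .asc (8-bit image formats ",
           "cannot hold float altitudes)")
    write_ascii_grid(raster, path, nodata)
  } else if (is.list(raster) && !is.null(raster$rgb)) {
    if (fmt == "asc") stop("RGB rasters must be written as .tif or .png")
    img <- pmin(pmax(raster$rgb, 0), 1)
    if (fmt == "tif") tiff::writeTIFF(img, path, bits.per.sample = 8)
    else png::writePNG(img, path)
    write_world_file(path, raster$origin_x, raster$origin_y, raster$gsd)
  } else stop("`raster` must be an elevation_raster or an rgb list")
  invisible(path)
}

write_ascii_grid <- function(raster, path, nodata = DEFAULT_NODATA) {
  m <- raster$values
  m[is.na(m)] <- nodata
  nr <- nrow(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)),
    paste("nrows", nr),
    paste("xllcorner", sprintf("%.17g", raster$origin_x)),
    paste("yllcorner", sprintf("%.17g", raster$origin_y - nr * raster$gsd)),
    paste("cellsize", sprintf("%.17g", raster$gsd)),
    paste("NODATA_value", sprintf("%.17g", nodata))
  ), con)
  rows <- apply(m, 1L, function(r) paste(sprintf("%.17g", r),
                                         collapse = " "))
  writeLines(rows, con)
  invisible(path)
}

#' Write a class mask
#'
#' Single-band file with the codes of [mask-codes] (nodata 0, ground 1,
#' canopy 2). PNG and TIFF are written 8-bit with a world-file sidecar;
#' `.asc` stores the integer codes as text.
#'
#' @param mask A [class_mask].
#' @param path Output file (`.png`, `.tif` or `.asc`).
#' @param raster Optional paired [elevation_raster]; with `strict = TRUE`
#'   the mask is validated against it before writing.
#' @param strict Validate shape and nodata agreement against `raster`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, raster = NULL, strict = !is.null(raster)) {
  stopifnot(inherits(mask, "class_mask"))
  if (strict) {
    if (is.null(raster)) stop("strict mask writing requires `raster`")
    class_mask(mask$labels, raster = raster, strict = TRUE)
  }
  fmt <- raster_format(path)
  if (fmt == "asc") {
    write_ascii_grid(
      elevation_raster(mask$labels, mask$origin_x, mask$origin_y, mask$gsd),
      path, nodata = -1)
  } else {
    img <- mask$labels / 255
    if (fmt == "tif") tiff::writeTIFF(img, path, bits.per.sample = 8)
    else png::writePNG(img, path)
    write_world_file(path, mask$origin_x, mask$origin_y, mask$gsd)
  }
  invisible(path)
}

#' Read a class mask
#'
#' @param path Mask file written by [write_mask] (or any single-band file
#'   with codes 0/1/2).
#' @return A [class_mask].
#' @export
read_mask <- function(path) {
  fmt <- raster_format(path)
  if (fmt == "asc") {
    r <- read_ascii_grid(path)
    lab <- r$values
    lab[is.na(lab)] <- MASK_NODATA
    return(class_mask(lab, r$origin_x, r$origin_y, r$gsd))
  }
  img <- if (fmt == "tif") tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  wf <- read_world_file(path)
  if (is.null(wf)) wf <- list(origin_x = 0, origin_y = nrow(img), gsd = 1)
  class_mask(round(img * 255), wf$origin_x, wf$origin_y, wf$gsd)
}

# ---- plot partitioning -----------------------------------------------------

#' Partition a raster into square plots
#'
#' Tiles the raster with square windows of side `plot_side` meters,
#' anchored at the raster origin, in row-major order. Interior windows
#' span `round(plot_side / gsd)` pixels; windows at the south and east
#' edges are truncated to the raster bounds so that every pixel belongs to
#' exactly one window. The 4.5 m default at the survey resolution of
#' 0.016 m/pixel gives 281-pixel windows.
#'
#' @param raster An [elevation_raster] (only its shape and `gsd` are used).
#' @param plot_side Plot edge length in meters (default 4.5).
#' @return A data.frame of plot windows with 0-based, half-open pixel
#'   bounds: columns `plot_i`, `plot_j` (grid indices, row-major),
#'   `row_start`, `row_stop`, `col_start`, `col_stop`.
#' @examples
#' r <- elevation_raster(matrix(0, 10, 10), gsd = 1)
#' partition_plots(r, 4.5)  # 3 x 3 windows of widths 4, 4, 2
#' @export
partition_plots <- function(raster, plot_side = 4.5) {
  stopifnot(inherits(raster, "elevation_raster"))
  if (!is.numeric(plot_side) || plot_side <= 0)
    stop("`plot_side` must be positive")
  if (plot_side < raster$gsd)
    stop("`plot_side` (", plot_side, " m) is smaller than one pixel (",
         raster$gsd, " m)")
  span <- as.integer(round(plot_side / raster$gsd))
  span <- max(span, 1L)
  d <- dim(raster$values)
  row_starts <- seq.int(0L, d[1] - 1L, by = span)
  col_starts <- seq.int(0L, d[2] - 1L, by = span)
  g <- expand.grid(j = seq_along(col_starts) - 1L,
                   i = seq_along(row_starts) - 1L)
  data.frame(
    plot_i = g$i, plot_j = g$j,
    row_start = row_starts[g$i + 1L],
    row_stop = pmin(row_starts[g$i + 1L] + span, d[1]),
    col_start = col_starts[g$j + 1L],
    col_stop = pmin(col_starts[g$j + 1L] + span, d[2])
  )
}

# Extract the value submatrix of one window (1-based internally).
window_values <- function(raster, window) {
  raster$values[(window$row_start + 1L):window$row_stop,
                (window$col_start + 1L):window$col_stop, drop = FALSE]
}

window_labels <- function(mask, window) {
  mask$labels[(window$row_start + 1L):window$row_stop,
              (window$col_start + 1L):window$col_stop, drop = FALSE]
}

# World coordinates of pixel centers in a window: list(x, y) matrices.
window_centers <- function(raster, window) {
  rows <- (window$row_start):(window$row_stop - 1L)
  cols <- (window$col_start):(window$col_stop - 1L)
  x <- raster$origin_x + (cols + 0.5) * raster$gsd
  y <- raster$origin_y - (rows + 0.5) * raster$gsd
  list(x = matrix(x, nrow = length(rows), ncol = length(cols), byrow = TRUE),
       y = matrix(y, nrow = length(rows), ncol = length(cols)))
}
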