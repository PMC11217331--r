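# Voxelized point-cloud reference volume.
#
# The reference ("true") canopy volume against which DSM-based estimates
# are scored: a ground-free canopy point cloud is discretized into cubic
# voxels (default 0.1 m) and the occupied-voxel count times the voxel
# volume is the measured canopy volume.

#' Voxelize a point cloud
#'
#' Assigns each point to the voxel `floor((p - origin) / voxel_size)` per
#' axis; duplicate assignments collapse to a single occupied voxel. A
#' point exactly on a voxel face belongs to the higher-index cell (floor
#' convention).
#'
#' @param points n x 3 matrix of `(x, y, z)` in meters.
#' @param voxel_size Cubic voxel edge in meters (default 0.1).
#' @param origin `"min_corner"` anchors the grid at the cloud's
#'   bounding-box minimum; `"zero"` at the world origin; or a numeric
#'   length-3 anchor.
#' @return Object of class `voxel_grid`: `voxel_size`, `origin`, and
#'   `occupied` (m x 3 integer matrix of unique voxel indices).
#' @examples
#' voxel_volume(voxelize(matrix(runif(300), 100, 3), 0.1))
#' @export
voxelize <- function(points, voxel_size = 0.1,
                     origin = c("min_corner", "zero")) {
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("cannot voxelize an empty point cloud")
  if (ncol(points) != 3L) stop("`points` must be an n x 3 matrix")
  if (voxel_size <= 0) stop("`voxel_size` must be positive")
  if (is.character(origin)) {
    origin <- match.arg(origin)
    origin <- if (origin == "min_corner") apply(points, 2, min) else c(0, 0, 0)
  }
  idx <- floor(sweep(points, 2, origin) / voxel_size)
  storage.mode(idx) <- "integer"
  occ <- unique(idx)
  dimnames(occ) <- list(NULL, c("i", "j", "k"))
  structure(list(voxel_size = voxel_size, origin = as.numeric(origin),
                 occupied = occ),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d occupied voxels of %g m -> %.4f m^3\n",
              nrow(x$occupied), x$voxel_size, voxel_volume(x)))
  invisible(x)
}

#' Volume of a voxel grid
#'
#' Occupied-voxel count times the volume of a single voxel.
#'
#' @param grid A [voxelize] result.
#' @return Volume in cubic meters.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  nrow(grid$occupied) * grid$voxel_size^3
}

#' Per-plot reference volumes from a point cloud
#'
#' Bins the points into the plot grid by their `(x, y)` coordinates and
#' voxelizes each plot's points independently (grid anchored at that
#' plot's cloud minimum, so plot volumes do not depend on one another).
#' Plots containing no points get volume 0. Points falling outside the
#' raster extent are dropped.
#'
#' @param points n x 3 matrix, georeferenced consistently with `raster`.
#' @param raster The [elevation_raster] defining the plot grid's
#'   georeference.
#' @param plots [partition_plots] data.frame.
#' @param voxel_size Voxel edge in meters (default 0.1).
#' @return data.frame `plot_i`, `plot_j`, `volume` (m^3), `n_points`.
#' @export
plot_reference_volumes <- function(points, raster, plots, voxel_size = 0.1) {
  points <- as.matrix(points)
  out <- data.frame(plot_i = plots$plot_i, plot_j = plots$plot_j,
                    volume = 0, n_points = 0L)
  if (nrow(points) == 0L) return(out)
  col <- floor((points[, 1] - raster$origin_x) / raster$gsd)
  row <- floor((raster$origin_y - points[, 2]) / raster$gsd)
  d <- dim(raster$values)
  keep <- row >= 0 & row < d[1] & col >= 0 & col < d[2]
  if (!any(keep)) return(out)
  row_starts <- sort(unique(plots$row_start))
  col_starts <- sort(unique(plots$col_start))
  pi_ <- findInterval(row[keep], row_starts) - 1L
  pj_ <- findInterval(col[keep], col_starts) - 1L
  grp <- split(which(keep), paste(pi_, pj_))
  key <- paste(out$plot_i, out$plot_j)
  for (g in names(grp)) {
    k <- match(g, key)
    if (is.na(k)) next
    sel <- grp[[g]]
    out$n_points[k] <- length(sel)
    out$volume[k] <- voxel_volume(
      voxelize(points[sel, , drop = FALSE], voxel_size, "min_corner"))
  }
  out
}

# ---- point-cloud files -----------------------------------------------------

#' Read a point cloud
#'
#' Supports whitespace-separated XYZ text (first three columns used) and
#' ascii PLY (vertex properties `x`, `y`, `z`; binary PLY is refused).
#'
#' @param path `.xyz`/`.txt` or `.ply` file.
#' @return n x 3 matrix with columns `x`, `y`, `z`.
#' @export
read_point_cloud <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") return(read_ply_ascii(path))
  m <- as.matrix(read.table(path))
  if (ncol(m) < 3L) stop("XYZ file must have at least 3 columns: ", path)
  m <- m[, 1:3, drop = FALSE]
  colnames(m) <- c("x", "y", "z")
  m
}

read_ply_ascii <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("PLY header has no end_header: ", path)
  hdr <- trimws(lines[2:(end - 1)])
  fmt <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1]))
    stop("only ascii PLY is supported: ", path)
  vline <- grep("^element vertex ", hdr, value = TRUE)
  if (!length(vline)) stop("PLY file has no vertex element: ", path)
  nv <- as.integer(strsplit(vline[1], "[[:space:]]+")[[1]][3])
  # property names of the vertex element, in declaration order
  velt <- grep("^element ", hdr)
  vstart <- match(vline[1], hdr)
  vend <- c(velt[velt > vstart], length(hdr) + 1L)[1] - 1L
  props <- hdr[(vstart + 1L):vend]
  props <- props[grepl("^property ", props)]
  pnames <- vapply(strsplit(props, "[[:space:]]+"), function(x) x[length(x)], "")
  need <- match(c("x", "y", "z"), pnames)
  if (anyNA(need)) stop("PLY vertex element lacks x/y/z properties: ", path)
  dat <- strsplit(trimws(lines[(end + 1L):(end + nv)]), "[[:space:]]+")
  m <- matrix(as.numeric(unlist(dat)), nrow = nv, byrow = TRUE)
  m <- m[, need, drop = FALSE]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Write a point cloud
#'
#' Format chosen by extension: whitespace XYZ text or ascii PLY.
#'
#' @param points n x 3 matrix.
#' @param path Output `.xyz`/`.txt` or `.ply` file.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(points, path) {
  points <- as.matrix(points)
  ext <- tolower(tools::file_ext(path))
  fmt <- function(m) apply(m, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " "))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(points)),
                 "property double x", "property double y", "property double z",
                 "end_header"), con)
    writeLines(fmt(points[, 1:3, drop = FALSE]), con)
  } else {
    writeLines(fmt(points[, 1:3, drop = FALSE]), path)
  }
  invisible(path)
}
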