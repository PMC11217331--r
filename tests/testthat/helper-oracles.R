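# Independent oracle implementations used to cross-check package routines.
# These deliberately use naive loops / base eigen(), not the package's code
# paths.

# Exhaustive Otsu: for every interior bin edge, compute between-class
# variance from the binned histogram by direct summation.
oracle_otsu <- function(values, bins = 256L) {
  v <- values[is.finite(values)]
  edges <- seq(min(v), max(v), length.out = bins + 1L)
  idx <- findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  mids <- (edges[-1L] + edges[-(bins + 1L)]) / 2
  n <- length(v)
  best <- -Inf; best_edge <- NA_real_
  for (k in 1:(bins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- n - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1):bins] * mids[(k + 1):bins]) / n1
    s <- (n0 / n) * (n1 / n) * (mu0 - mu1)^2
    if (s > best) { best <- s; best_edge <- edges[k + 1L] }
  }
  best_edge
}

# Total-least-squares plane through a point set via base eigen().
oracle_tls_plane <- function(pts) {
  ctr <- colMeans(pts)
  cc <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  nrm <- ev$vectors[, 3]
  if (nrm[3] < 0) nrm <- -nrm
  list(normal = nrm, offset = -sum(nrm * ctr))
}

# Naive per-element metric recomputations.
oracle_miou <- function(tp, tn, fp, fn)
  100 * ((tp / (tp + fp + fn)) + (tn / (tn + fp + fn))) / 2
oracle_mpa <- function(tp, tn, fp, fn)
  100 * ((tp / (tp + fn)) + (tn / (tn + fp))) / 2
oracle_rmse <- function(m, t) {
  s <- 0
  for (i in seq_along(m)) s <- s + (m[i] - t[i])^2
  sqrt(s / length(m))
}
oracle_mape_truth <- function(m, t) {
  s <- 0
  for (i in seq_along(m)) s <- s + abs(t[i] - m[i]) / t[i]
  100 * s / length(m)
}

# Naive confusion counting by explicit double loop over a small grid.
oracle_confusion <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j]; t <- truth[i, j]
    if (p == 0L || t == 0L) next
    if (p == 2L && t == 2L) tp <- tp + 1L
    else if (p == 1L && t == 1L) tn <- tn + 1L
    else if (p == 2L && t == 1L) fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Brute-force tree height: scan every pixel center, keep those inside the
# disc, return max - min.
oracle_tree_height_raster <- function(raster, bx, by, radius) {
  d <- dim(raster$values)
  zs <- c()
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    x <- raster$origin_x + (c - 0.5) * raster$gsd
    y <- raster$origin_y - (r - 0.5) * raster$gsd
    if ((x - bx)^2 + (y - by)^2 <= radius^2 && !is.na(raster$values[r, c]))
      zs <- c(zs, raster$values[r, c])
  }
  if (length(zs) < 2) return(NA_real_)
  max(zs) - min(zs)
}

# Small flat test raster.
flat_raster <- function(nr = 10, nc = 10, value = 0, gsd = 1)
  elevation_raster(matrix(value, nr, nc), gsd = gsd)
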