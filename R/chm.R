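#' Canopy height model from DSM and DTM
#'
#' Cellwise DSM minus DTM, with negative heights clamped to zero and nodata
#' propagated. If the grids are not co-registered the DTM is resampled onto
#' the DSM grid by bilinear interpolation (terrain is smooth, so bilinear is
#' adequate).
#'
#' @param dsm digital surface model `raster_grid`.
#' @param dtm digital terrain model `raster_grid`.
#' @return CHM `raster_grid` on the DSM grid.
#' @export
compute_chm <- function(dsm, dtm) {
  ea <- grid_extent(dsm); eb <- grid_extent(dtm)
  if (ea["xmin"] >= eb["xmax"] || eb["xmin"] >= ea["xmax"] ||
      ea["ymin"] >= eb["ymax"] || eb["ymin"] >= ea["ymax"]) {
    stop_invalid("DSM and DTM extents are disjoint: cannot align")
  }
  if (!grid_compatible(dsm, dtm)) dtm <- resample_to(dtm, dsm)
  a <- dsm$values; b <- dtm$values
  nod <- a == dsm$nodata | b == dtm$nodata | is.na(a) | is.na(b)
  v <- pmax(a - b, 0)
  v[nod] <- dsm$nodata
  raster_grid(v, dsm$cell_size, dsm$origin, dsm$nodata)
}

#' Reconstruct a DTM by inverse-distance-weighted ground sampling
#'
#' Emulates the point-sampling terrain technique: ground elevations are read
#' from the DSM at user-supplied ground locations, then every cell of the
#' output grid is the inverse-distance-weighted mean (weights `d^-power`) of
#' its `k_neighbors` nearest samples. A cell whose center coincides with a
#' sample (distance < cell_size/10) returns that sample's elevation exactly.
#'
#' @param dsm `raster_grid` the elevations are sampled from and whose
#'   geometry the output inherits.
#' @param ground_points data.frame or matrix of ground sample locations with
#'   columns/cols `x`, `y` (map meters).
#' @param power IDW exponent (default 2).
#' @param k_neighbors number of nearest samples per cell (default 12).
#' @return a DTM `raster_grid` on the DSM grid.
#' @export
sample_dtm_idw <- function(dsm, ground_points, power = 2, k_neighbors = 12) {
  gp <- as.matrix(as.data.frame(ground_points)[, c("x", "y")])
  ij <- cell_index(dsm, gp[, 1], gp[, 2])
  ok <- !is.na(ij$row)
  gp <- gp[ok, , drop = FALSE]; ij <- ij[ok, , drop = FALSE]
  if (nrow(gp) < 3) stop_invalid("need at least 3 ground samples inside the DSM")
  zs <- dsm$values[cbind(ij$row, ij$col)]
  keep <- zs != dsm$nodata & is.finite(zs)
  gp <- gp[keep, , drop = FALSE]; zs <- zs[keep]
  if (nrow(gp) < 3) stop_invalid("need at least 3 ground samples with valid elevation")
  k <- min(k_neighbors, nrow(gp))
  cc <- cell_centers(dsm)
  nrows <- nrow(dsm$values); ncols <- ncol(dsm$values)
  centers <- cbind(rep(cc$x, each = nrows), rep(cc$y, times = ncols))
  nn <- FNN::get.knnx(gp, centers, k = k)
  d <- nn$nn.dist
  zmat <- matrix(zs[nn$nn.index], nrow = nrow(d))
  snap <- d[, 1] < dsm$cell_size / 10
  w <- d^(-power)
  v <- rowSums(w * zmat) / rowSums(w)
  v[snap] <- zmat[snap, 1]
  raster_grid(matrix(v, nrows, ncols), dsm$cell_size, dsm$origin, dsm$nodata)
}

#' Stratified random ground-sample locations
#'
#' Divides the extent into a near-square grid of strata and draws one random
#' location per stratum until `n` points are placed. If a canopy mask is
#' supplied, locations falling on masked (canopy) cells are re-drawn within
#' the stratum, so samples land on visible ground.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)`.
#' @param n number of points (default 100).
#' @param seed integer RNG seed.
#' @param avoid_mask optional binary `raster_grid` (1 = canopy) of cells to
#'   avoid.
#' @param max_tries re-draws per stratum before giving up on it.
#' @return data.frame with columns `x`, `y`.
#' @export
stratified_ground_points <- function(extent, n = 100, seed = 1,
                                     avoid_mask = NULL, max_tries = 50) {
  nx <- ceiling(sqrt(n * (extent[3] - extent[1]) / (extent[4] - extent[2])))
  ny <- ceiling(n / nx)
  xs <- seq(extent[1], extent[3], length.out = nx + 1)
  ys <- seq(extent[2], extent[4], length.out = ny + 1)
  strata <- expand.grid(i = seq_len(nx), j = seq_len(ny))
  strata <- strata[seq_len(min(nrow(strata), n)), ]
  with_seed(seed, {
    pts <- lapply(seq_len(nrow(strata)), function(s) {
      i <- strata$i[s]; j <- strata$j[s]
      for (tr in seq_len(max_tries)) {
        px <- stats::runif(1, xs[i], xs[i + 1])
        py <- stats::runif(1, ys[j], ys[j + 1])
        if (is.null(avoid_mask)) return(c(px, py))
        ij <- cell_index(avoid_mask, px, py)
        if (is.na(ij$row) || avoid_mask$values[ij$row, ij$col] == 0) {
          return(c(px, py))
        }
      }
      NULL
    })
    pts <- do.call(rbind, pts[!vapply(pts, is.null, TRUE)])
    data.frame(x = pts[, 1], y = pts[, 2])
  })
}

#' Reclassify a CHM into a binary canopy mask
#'
#' @param chm canopy height model `raster_grid`.
#' @param height_threshold height above ground separating canopy from other
#'   features, meters (default 0.5).
#' @return a `raster_grid` of 0/1 values (1 = canopy); nodata cells are 0.
#' @export
reclassify_canopy <- function(chm, height_threshold = 0.5) {
  if (height_threshold <= 0) stop_invalid("height_threshold must be positive")
  v <- chm$values
  mask <- (v >= height_threshold) & (v != chm$nodata) & is.finite(v)
  raster_grid(mask * 1, chm$cell_size, chm$origin, nodata = -1)
}
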