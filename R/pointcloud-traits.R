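#' Correct the systematic tilt of a point cloud
#'
#' Sensor clouds often carry a small angular bias: the whole scene is rotated
#' a few degrees off level. The ground plane is estimated by pooling, within
#' each block of a coarse horizontal grid, the points in the lowest
#' `ground_quantile` of that block's z values (so canopy-dominated blocks
#' contribute little), fitting `z ~ x + y` by least squares with one
#' reweighting pass that drops residuals beyond 2 standard deviations, and
#' the cloud is then rigidly rotated about the centroid of the ground points
#' so the fitted normal becomes vertical. The correction is a pure rotation:
#' pairwise distances are preserved.
#'
#' @param cloud point-cloud data.frame with `x`, `y`, `z`.
#' @param ground_quantile fraction of lowest points per block treated as
#'   ground candidates, in (0, 0.5] (default 0.1).
#' @param n_blocks number of grid blocks per axis (default 8).
#' @return the leveled cloud, with attributes `tilt_deg` (recovered tilt
#'   angle in degrees) and `rotation` (the 3x3 matrix applied).
#' @export
correct_tilt <- function(cloud, ground_quantile = 0.1, n_blocks = 8) {
  if (nrow(cloud) < 10) stop_invalid("need at least 10 points to fit a ground plane")
  if (!(ground_quantile > 0 && ground_quantile <= 0.5)) {
    stop_invalid("ground_quantile must be in (0, 0.5]")
  }
  P <- as.matrix(cloud[, c("x", "y", "z")])
  bx <- cut(P[, 1], n_blocks, labels = FALSE)
  by <- cut(P[, 2], n_blocks, labels = FALSE)
  block <- (bx - 1L) * n_blocks + by
  ground_idx <- unlist(lapply(split(seq_len(nrow(P)), block), function(ii) {
    if (length(ii) < 3) return(integer(0))
    zi <- P[ii, 3]
    ii[zi <= stats::quantile(zi, ground_quantile)]
  }), use.names = FALSE)
  G <- P[ground_idx, , drop = FALSE]
  fit_plane <- function(M) {
    X <- cbind(1, M[, 1], M[, 2])
    if (qr(X)$rank < 3) stop_invalid("ground points are collinear: cannot fit a plane")
    stats::lm.fit(X, M[, 3])
  }
  f <- fit_plane(G)
  # iterate 2-sd rejection: crown-bottom points caught in canopy-only
  # blocks sit far above the plane and are shed over a few passes
  for (pass in 1:5) {
    keep <- abs(f$residuals) <= 2 * stats::sd(f$residuals)
    if (all(keep) || sum(keep) < 10) break
    G <- G[keep, , drop = FALSE]
    f <- fit_plane(G)
  }
  b <- f$coefficients[2]; cxy <- f$coefficients[3]
  normal <- c(-b, -cxy, 1) / sqrt(b^2 + cxy^2 + 1)
  angle <- acos(min(1, normal[3]))
  out <- cloud
  R <- diag(3)
  if (angle > 1e-9) {
    axis <- cross3(normal, c(0, 0, 1))
    R <- rotation_matrix(axis, angle)
    ctr <- colMeans(G)
    Q <- sweep(sweep(P, 2, ctr) %*% t(R), 2, ctr, `+`)
    out$x <- Q[, 1]; out$y <- Q[, 2]; out$z <- Q[, 3]
  }
  attr(out, "tilt_deg") <- angle * 180 / pi
  attr(out, "rotation") <- R
  out
}

#' Statistical outlier removal and optional voxel down-sampling
#'
#' Drops points whose mean distance to their `k` nearest neighbours exceeds
#' the global mean by more than `sd_mult` standard deviations, then
#' optionally thins the cloud to one centroid per occupied voxel (the
#' down-sampling used for dense terrestrial-LiDAR clouds).
#'
#' @param cloud point-cloud data.frame with `x`, `y`, `z`.
#' @param k number of neighbours (default 8).
#' @param sd_mult outlier threshold in standard deviations (default 2);
#'   `Inf` disables outlier removal.
#' @param voxel_downsample voxel edge in meters, or `NULL` to skip.
#' @return the filtered cloud. Outlier removal preserves all columns;
#'   voxel down-sampling returns centroid coordinates only.
#' @export
filter_cloud <- function(cloud, k = 8, sd_mult = 2, voxel_downsample = NULL) {
  if (k < 1) stop_invalid("k must be >= 1")
  out <- cloud
  if (nrow(cloud) < k + 1) {
    warning("cloud smaller than k + 1: returned unchanged")
  } else if (is.finite(sd_mult)) {
    P <- as.matrix(cloud[, c("x", "y", "z")])
    nn <- FNN::get.knn(P, k = k)
    md <- rowMeans(nn$nn.dist)
    out <- cloud[md <= mean(md) + sd_mult * stats::sd(md), , drop = FALSE]
  }
  if (!is.null(voxel_downsample)) {
    if (voxel_downsample <= 0) stop_invalid("voxel_downsample must be positive")
    P <- as.matrix(out[, c("x", "y", "z")])
    anchor <- apply(P, 2, min)
    key <- voxel_key(P, anchor, voxel_downsample)
    id <- paste(key[, 1], key[, 2], key[, 3])
    ctr <- rowsum(P, id)
    counts <- as.vector(rowsum(rep(1, nrow(P)), id))
    out <- data.frame(x = ctr[, 1] / counts, y = ctr[, 2] / counts,
                      z = ctr[, 3] / counts)
  }
  rownames(out) <- NULL
  out
}

#' Segment a single tree from a cloud by its horizontal extent
#'
#' Keeps points whose (x, y) fall in the half-open rectangle
#' `[xmin, xmax) x [ymin, ymax)`, so adjacent touching extents never share
#' points. Ground points inside the extent are retained, since the height
#' computation needs the local minimum z.
#'
#' @param cloud point-cloud data.frame.
#' @param extent `c(xmin, ymin, xmax, ymax)`, or `NULL` when `center` and
#'   `size` are given.
#' @param center optional `c(x, y)` tree center.
#' @param size optional `c(length, width)` of a rectangle around `center`.
#' @param tree_id identifier used in error messages.
#' @return the per-tree point cloud.
#' @export
segment_tree <- function(cloud, extent = NULL, center = NULL, size = NULL,
                         tree_id = NA) {
  if (is.null(extent)) {
    if (is.null(center) || is.null(size)) {
      stop_invalid("provide either extent or center + size")
    }
    extent <- c(center[1] - size[1] / 2, center[2] - size[2] / 2,
                center[1] + size[1] / 2, center[2] + size[2] / 2)
  }
  if (!(extent[3] > extent[1] && extent[4] > extent[2])) {
    stop_invalid("degenerate extent")
  }
  sel <- cloud$x >= extent[1] & cloud$x < extent[3] &
    cloud$y >= extent[2] & cloud$y < extent[4]
  if (!any(sel)) stop_invalid("no points in the extent of tree ", tree_id)
  out <- cloud[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tree height from a segmented point cloud
#'
#' `H = Zmax - Zmin` over the tree's points (ground included, so Zmin sits
#' at the terrain surface).
#'
#' @param tree_cloud per-tree point-cloud data.frame.
#' @return height in meters.
#' @export
tree_height <- function(tree_cloud) {
  if (nrow(tree_cloud) < 2) stop_invalid("need at least 2 points for a height")
  max(tree_cloud$z) - min(tree_cloud$z)
}

#' Delineate the canopy crown of a segmented tree
#'
#' Keeps points at or above `Zmin + trunk_fraction * H`, removing the trunk
#' and ground so that crown-volume estimates cover the photosynthetic crown
#' only. The default 0.20 is the complement of the 0.80 crown ratio used by
#' the pyramid volume formulas.
#'
#' @param tree_cloud per-tree point-cloud data.frame.
#' @param trunk_fraction fraction of the height cut away from below
#'   (default 0.20).
#' @return the crown point cloud.
#' @export
delineate_crown <- function(tree_cloud, trunk_fraction = 0.20) {
  h <- tree_height(tree_cloud)
  cut <- min(tree_cloud$z) + trunk_fraction * h
  out <- tree_cloud[tree_cloud$z >= cut, , drop = FALSE]
  if (nrow(out) == 0) stop_invalid("empty crown after trunk cut")
  rownames(out) <- NULL
  out
}

#' Voxel-grid crown volume
#'
#' Counts the distinct voxels occupied by crown points on a grid anchored at
#' the crown's minimum corner (half-open cells) and returns
#' `count * voxel_size^3`. The anchoring convention changes the count by at
#' most one surface shell of voxels.
#'
#' @param crown crown point-cloud data.frame.
#' @param voxel_size voxel edge in meters (default 0.1).
#' @return volume in cubic meters (an exact multiple of `voxel_size^3`).
#' @export
voxel_grid_volume <- function(crown, voxel_size = 0.1) {
  if (voxel_size <= 0) stop_invalid("voxel_size must be positive")
  if (nrow(crown) < 1) stop_invalid("empty crown")
  P <- as.matrix(crown[, c("x", "y", "z")])
  anchor <- apply(P, 2, min)
  key <- voxel_key(P, anchor, voxel_size)
  n_occ <- length(unique(paste(key[, 1], key[, 2], key[, 3])))
  n_occ * voxel_size^3
}

# integer voxel indices; the 1e-9 nudge keeps points that sit numerically on
# a voxel boundary in the cell their exact coordinate belongs to
voxel_key <- function(P, anchor, voxel) {
  floor(sweep(P, 2, anchor) / voxel + 1e-9)
}

#' Tetrahedral (convex-hull) crown volume
#'
#' The crown points are meshed into tetrahedra spanning their convex hull;
#' the volume is the sum of tetrahedron volumes, which equals the convex
#' hull volume of the point set. For points sampled on a convex crown
#' surface this is an inscribed estimate and approaches the true volume
#' from below.
#'
#' @param crown crown point-cloud data.frame with at least 4 non-coplanar
#'   points.
#' @return volume in cubic meters.
#' @export
hull_volume <- function(crown) {
  P <- as.matrix(crown[, c("x", "y", "z")])
  convex_hull_volume(P)
}
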