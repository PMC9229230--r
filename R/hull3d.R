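#' Convex hull volume of a 3D point set
#'
#' Incremental construction: an initial tetrahedron of extreme points is
#' grown point by point; for each point outside the current hull the visible
#' faces are removed and the horizon edges are joined to the point, keeping
#' all face normals outward. The volume is the sum of signed tetrahedron
#' volumes between each face and the hull centroid — the tetrahedral
#' decomposition of the hull.
#'
#' @param P numeric matrix with 3 columns (x, y, z).
#' @return hull volume in cubic units.
#' @export
convex_hull_volume <- function(P) {
  P <- unique(as.matrix(P))
  storage.mode(P) <- "double"
  if (nrow(P) < 4) stop_invalid("need at least 4 distinct points")
  scale <- max(apply(P, 2, function(v) diff(range(v))))
  if (scale == 0) stop_invalid("degenerate geometry: all points coincide")
  eps <- 1e-12 * scale^2 # visibility tolerance on (unnormalized) plane offsets

  # initial simplex from extreme points
  i1 <- which.min(P[, 1])
  d1 <- colSums((t(P) - P[i1, ])^2)
  i2 <- which.max(d1)
  e <- P[i2, ] - P[i1, ]
  cr <- t(apply(sweep(P, 2, P[i1, ]), 1, function(v) cross3(e, v)))
  i3 <- which.max(rowSums(cr^2))
  n0 <- cross3(e, P[i3, ] - P[i1, ])
  dist_plane <- abs(sweep(P, 2, P[i1, ]) %*% n0)
  i4 <- which.max(dist_plane)
  if (sqrt(sum((P[i2, ] - P[i1, ])^2)) < 1e-12 * scale ||
      sqrt(sum(cr[i3, ]^2)) < 1e-12 * scale^2 ||
      dist_plane[i4] < 1e-10 * scale^3) {
    stop_invalid("degenerate geometry: points are collinear or coplanar")
  }

  faces <- rbind(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  ctr <- colMeans(P[c(i1, i2, i3, i4), ])
  orient <- function(f) {
    n <- cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
    if (sum(n * (ctr - P[f[1], ])) > 0) f[c(1, 3, 2)] else f
  }
  faces <- t(apply(faces, 1, orient))
  face_normal <- function(f) cross3(P[f[2], ] - P[f[1], ], P[f[3], ] - P[f[1], ])
  normals <- t(apply(faces, 1, face_normal))
  offsets <- rowSums(normals * P[faces[, 1], , drop = FALSE])

  rest <- setdiff(seq_len(nrow(P)), c(i1, i2, i3, i4))
  for (p in rest) {
    vis <- which(as.vector(normals %*% P[p, ]) - offsets > eps)
    if (!length(vis)) next
    vf <- faces[vis, , drop = FALSE]
    dir_edges <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(3, 1)])
    ek <- paste(dir_edges[, 1], dir_edges[, 2])
    rk <- paste(dir_edges[, 2], dir_edges[, 1])
    horizon <- dir_edges[!(ek %in% rk), , drop = FALSE]
    new_faces <- cbind(horizon, p)
    faces <- rbind(faces[-vis, , drop = FALSE], new_faces)
    new_n <- t(apply(new_faces, 1, face_normal))
    normals <- rbind(normals[-vis, , drop = FALSE], new_n)
    offsets <- c(offsets[-vis],
                 rowSums(new_n * P[new_faces[, 1], , drop = FALSE]))
  }

  hc <- colMeans(P[unique(as.vector(faces)), , drop = FALSE])
  v1 <- P[faces[, 1], , drop = FALSE] - rep(hc, each = nrow(faces))
  v2 <- P[faces[, 2], , drop = FALSE] - rep(hc, each = nrow(faces))
  v3 <- P[faces[, 3], , drop = FALSE] - rep(hc, each = nrow(faces))
  dets <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
    v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
    v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  abs(sum(dets)) / 6
}
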