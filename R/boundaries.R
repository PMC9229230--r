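#' Per-tree canopy boundary
#'
#' @param tree_id integer tree identifier.
#' @param kind one of `"polygon"`, `"box"`, `"circle"`.
#' @param geometry polygon/box: a two-column matrix of vertices (map meters,
#'   closed implicitly); circle: `list(center = c(x, y), radius = r)`.
#' @param area enclosed area in square meters.
#' @return an object of class `tree_boundary`.
#' @export
tree_boundary <- function(tree_id, kind, geometry, area) {
  kind <- match.arg(kind, c("polygon", "box", "circle"))
  if (!is.finite(area) || area <= 0) stop_invalid("boundary area must be > 0")
  structure(list(tree_id = tree_id, kind = kind, geometry = geometry,
                 area = area), class = "tree_boundary")
}

#' @export
print.tree_boundary <- function(x, ...) {
  cat(sprintf("tree_boundary: tree %s, %s, area %.3f m2\n",
              x$tree_id, x$kind, x$area))
  invisible(x)
}

# 8-connected component labeling of a logical matrix (flood fill)
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  cur <- 0L
  off <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  off <- off[!(off[, 1] == 0 & off[, 2] == 0), ]
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      lin <- queue[length(queue)]
      queue <- queue[-length(queue)]
      i <- (lin - 1L) %% nr + 1L; j <- (lin - 1L) %/% nr + 1L
      ni <- i + off[, 1]; nj <- j + off[, 2]
      okn <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      nlin <- (nj[okn] - 1L) * nr + ni[okn]
      nlin <- nlin[mask[nlin] & lab[nlin] == 0L]
      lab[nlin] <- cur
      queue <- c(queue, nlin)
    }
  }
  lab
}

# trace the outer outline of a set of cells (i, j) as a closed polygon in
# lattice corner coordinates; interior kept on the left of each directed edge
trace_outline <- function(cells, nr, nc) {
  key <- function(i, j) (j) * (nr + 2L) + i # corner lattice key, i in 0..nr
  inset <- new.env(hash = TRUE)
  for (r in seq_len(nrow(cells))) {
    assign(as.character((cells[r, 2] - 1L) * nr + cells[r, 1]), TRUE, inset)
  }
  incomp <- function(i, j) {
    if (i < 1L || i > nr || j < 1L || j > nc) return(FALSE)
    exists(as.character((j - 1L) * nr + i), inset)
  }
  # directed boundary edges between corner lattice points (i = row line
  # 0..nr top-to-bottom, j = col line 0..nc left-to-right)
  froms <- character(0); edges <- list()
  add_edge <- function(a, b) {
    k <- paste(a, collapse = ",")
    edges[[length(edges) + 1L]] <<- list(from = a, to = b)
    froms[length(froms) + 1L] <<- k
  }
  for (r in seq_len(nrow(cells))) {
    i <- cells[r, 1]; j <- cells[r, 2]
    if (!incomp(i - 1L, j)) add_edge(c(i - 1L, j), c(i - 1L, j - 1L)) # top: -x
    if (!incomp(i + 1L, j)) add_edge(c(i, j - 1L), c(i, j))           # bottom: +x
    if (!incomp(i, j - 1L)) add_edge(c(i - 1L, j - 1L), c(i, j - 1L)) # left: down
    if (!incomp(i, j + 1L)) add_edge(c(i, j), c(i - 1L, j))           # right: up
  }
  used <- rep(FALSE, length(edges))
  loops <- list()
  emap <- split(seq_along(edges), froms)
  repeat {
    s <- which(!used)[1]
    if (is.na(s)) break
    path <- list(edges[[s]]$from)
    cur <- edges[[s]]$to
    used[s] <- TRUE
    while (!identical(cur, path[[1]])) {
      path[[length(path) + 1L]] <- cur
      cand <- emap[[paste(cur, collapse = ",")]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break # should not happen for well-formed boundaries
      used[cand[1]] <- TRUE
      cur <- edges[[cand[1]]]$to
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, path)
  }
  # outer outline = loop of largest absolute shoelace area
  areas <- vapply(loops, function(L) abs(shoelace_area(L)), 0)
  loops[[which.max(areas)]]
}

#' Shoelace area of a polygon
#'
#' @param verts two-column matrix of vertices (closed implicitly).
#' @return signed area (positive if counter-clockwise).
#' @export
shoelace_area <- function(verts) {
  x <- verts[, 1]; y <- verts[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  sum(x * y2 - x2 * y) / 2
}

#' Point-in-polygon test (even-odd ray crossing)
#'
#' @param px,py point coordinates (vectorized).
#' @param verts two-column polygon vertex matrix.
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, verts) {
  n <- nrow(verts)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- verts[i, 1]; yi <- verts[i, 2]
    xj <- verts[j, 1]; yj <- verts[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# --- minimum enclosing circle (Welzl, on 2D convex hull points) ---------

circle_two <- function(p, q) {
  list(center = (p + q) / 2, radius = sqrt(sum((p - q)^2)) / 2)
}

circle_three <- function(a, b, cc) {
  d <- 2 * (a[1] * (b[2] - cc[2]) + b[1] * (cc[2] - a[2]) + cc[1] * (a[2] - b[2]))
  if (abs(d) < 1e-14) return(NULL)
  ux <- (sum(a^2) * (b[2] - cc[2]) + sum(b^2) * (cc[2] - a[2]) +
           sum(cc^2) * (a[2] - b[2])) / d
  uy <- (sum(a^2) * (cc[1] - b[1]) + sum(b^2) * (a[1] - cc[1]) +
           sum(cc^2) * (b[1] - a[1])) / d
  ctr <- c(ux, uy)
  list(center = ctr, radius = sqrt(sum((a - ctr)^2)))
}

in_circle <- function(circ, p, tol = 1e-10) {
  sqrt(sum((p - circ$center)^2)) <= circ$radius * (1 + tol) + tol
}

welzl <- function(P, R) {
  if (nrow(P) == 0 || nrow(R) == 3) {
    if (nrow(R) == 0) return(list(center = c(0, 0), radius = 0))
    if (nrow(R) == 1) return(list(center = R[1, ], radius = 0))
    if (nrow(R) == 2) return(circle_two(R[1, ], R[2, ]))
    circ <- circle_three(R[1, ], R[2, ], R[3, ])
    if (is.null(circ)) { # collinear supports: widest pair
      d <- as.matrix(stats::dist(R))
      ij <- which(d == max(d), arr.ind = TRUE)[1, ]
      return(circle_two(R[ij[1], ], R[ij[2], ]))
    }
    return(circ)
  }
  p <- P[nrow(P), ]
  circ <- welzl(P[-nrow(P), , drop = FALSE], R)
  if (in_circle(circ, p)) return(circ)
  welzl(P[-nrow(P), , drop = FALSE], rbind(R, p))
}

#' Minimum enclosing circle of a 2D point set
#'
#' Welzl's randomized algorithm, run on the convex hull of the input (the
#' enclosing circle depends only on hull points), so recursion depth stays
#' small for large rasterized footprints.
#'
#' @param pts two-column matrix of points.
#' @return `list(center = c(x, y), radius = r)`.
#' @export
min_enclosing_circle <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) == 1) return(list(center = pts[1, ], radius = 0))
  if (nrow(pts) > 3) pts <- pts[grDevices::chull(pts), , drop = FALSE]
  pts <- pts[with_seed(7L, sample(nrow(pts))), , drop = FALSE]
  welzl(pts, pts[0, , drop = FALSE])
}

#' Delineate per-tree canopy boundaries from a binary mask
#'
#' Within each tree's search rectangle the largest 8-connected canopy
#' component is found; the boundary is then one of: the traced outline of
#' the component (`polygon`, area by the shoelace formula), the axis-aligned
#' bounding rectangle of the component cells (`box`), or the minimum
#' enclosing circle of the component's cell centers (`circle`).
#'
#' @param mask binary canopy `raster_grid` from [reclassify_canopy()].
#' @param tree_extents data.frame with columns `tree_id`, `xmin`, `ymin`,
#'   `xmax`, `ymax` (map meters).
#' @param kind boundary geometry: `"polygon"`, `"box"` or `"circle"`.
#' @return list of [tree_boundary()] objects, one per tree.
#' @export
extract_boundaries <- function(mask, tree_extents, kind = "polygon") {
  kind <- match.arg(kind, c("polygon", "box", "circle"))
  cc <- cell_centers(mask)
  cs <- mask$cell_size
  lapply(seq_len(nrow(tree_extents)), function(t) {
    te <- tree_extents[t, ]
    cols <- which(cc$x >= te$xmin & cc$x < te$xmax)
    rows <- which(cc$y > te$ymin & cc$y <= te$ymax)
    sub <- mask$values[rows, cols, drop = FALSE] == 1
    if (!any(sub)) {
      stop_invalid("no canopy cells in the extent of tree ", te$tree_id)
    }
    lab <- label_components(sub)
    big <- which.max(tabulate(lab[lab > 0L]))
    cells <- which(lab == big, arr.ind = TRUE)
    # map lattice: corner (i, j) of the submatrix -> map coordinates
    x_of <- function(j) mask$origin[1] + (cols[1] - 1L + j) * cs
    y_of <- function(i) mask$origin[2] - (rows[1] - 1L + i) * cs
    if (kind == "polygon") {
      L <- trace_outline(cells, nrow(sub), ncol(sub))
      verts <- cbind(x_of(L[, 2]), y_of(L[, 1]))
      tree_boundary(te$tree_id, "polygon", verts, abs(shoelace_area(verts)))
    } else if (kind == "box") {
      xmin <- x_of(min(cells[, 2]) - 1L); xmax <- x_of(max(cells[, 2]))
      ymax <- y_of(min(cells[, 1]) - 1L); ymin <- y_of(max(cells[, 1]))
      verts <- cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
      tree_boundary(te$tree_id, "box", verts, (xmax - xmin) * (ymax - ymin))
    } else {
      ctrs <- cbind(x_of(cells[, 2]) - cs / 2, y_of(cells[, 1]) + cs / 2)
      circ <- min_enclosing_circle(ctrs)
      tree_boundary(te$tree_id, "circle", circ, pi * circ$radius^2)
    }
  })
}

#' Zonal maximum height within a tree boundary
#'
#' The maximum CHM value over cells whose centers fall inside the boundary
#' geometry; nodata cells are ignored.
#'
#' @param chm canopy height model `raster_grid`.
#' @param boundary a [tree_boundary()].
#' @return maximum height in meters.
#' @export
zonal_max_height <- function(chm, boundary) {
  cc <- cell_centers(chm)
  nr <- nrow(chm$values); ncl <- ncol(chm$values)
  px <- rep(cc$x, each = nr); py <- rep(cc$y, times = ncl)
  inside <- if (boundary$kind == "circle") {
    (px - boundary$geometry$center[1])^2 + (py - boundary$geometry$center[2])^2 <=
      boundary$geometry$radius^2
  } else {
    bb <- apply(boundary$geometry, 2, range)
    pre <- px >= bb[1, 1] & px <= bb[2, 1] & py >= bb[1, 2] & py <= bb[2, 2]
    ins <- pre
    ins[pre] <- point_in_polygon(px[pre], py[pre], boundary$geometry)
    ins
  }
  v <- as.vector(chm$values)[inside]
  v <- v[v != chm$nodata & is.finite(v)]
  if (!length(v)) stop_invalid("boundary of tree ", boundary$tree_id,
                               " overlaps no valid CHM cell")
  max(v)
}

#' Pyramid crown volume from a boundary and a maximum height
#'
#' The crown is modeled as a pyramid (polygon/box base) or cone (circle
#' base) over the boundary area, with effective height
#' `crown_ratio * max_height` so that only the photosynthetic crown — not
#' the trunk — contributes: `V = A * H_eff / 3` for polygon and box,
#' `V = pi * r^2 * H_eff / 3` for the circle.
#'
#' @param boundary a [tree_boundary()].
#' @param max_height maximum tree height in meters (zonal CHM maximum).
#' @param crown_ratio crown fraction of total height (default 0.80).
#' @return crown volume in cubic meters.
#' @export
pyramid_crown_volume <- function(boundary, max_height, crown_ratio = 0.80) {
  if (max_height <= 0) stop_invalid("max_height must be positive")
  if (!(crown_ratio > 0 && crown_ratio <= 1)) {
    stop_invalid("crown_ratio must be in (0, 1]")
  }
  if (boundary$area <= 0) {
    warning("zero boundary area: volume 0")
    return(0)
  }
  h_eff <- crown_ratio * max_height
  if (boundary$kind == "circle") {
    pi * boundary$geometry$radius^2 * h_eff / 3
  } else {
    boundary$area * h_eff / 3
  }
}
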