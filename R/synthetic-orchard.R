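#' Generate a smooth synthetic terrain raster
#'
#' Elevation is a tilted plane plus a Gaussian random field smoothed with a
#' separable Gaussian kernel and rescaled to the requested roughness
#' standard deviation. With `roughness_sd = 0` the surface is exactly planar.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` in meters.
#' @param cell_size cell edge in meters, > 0.
#' @param mean_elevation mean elevation in meters (default 700, a Palouse
#'   hillslope scale).
#' @param slope terrain gradient in m/m: a single number (gradient along +x)
#'   or a length-2 vector `c(dz/dx, dz/dy)`.
#' @param roughness_sd standard deviation in meters of the smooth random
#'   departure from the plane.
#' @param seed integer RNG seed; output is reproducible given the seed.
#' @param smooth_cells Gaussian smoothing sigma of the roughness field, in
#'   cells (default 60, i.e. a ~3 m correlation scale at the default 0.05 m cell: terrain undulates between rows but is smooth at single-tree scale).
#' @return a `raster_grid` of elevations.
#' @export
generate_terrain <- function(extent, cell_size, mean_elevation = 700,
                             slope = 0.01, roughness_sd = 0.05, seed = 1,
                             smooth_cells = 60) {
  if (cell_size <= 0) stop_invalid("cell_size must be positive")
  if (!(extent[3] > extent[1] && extent[4] > extent[2])) {
    stop_invalid("degenerate extent")
  }
  if (length(slope) == 1) slope <- c(slope, 0)
  ncols <- max(1L, ceiling((extent[3] - extent[1]) / cell_size))
  nrows <- max(1L, ceiling((extent[4] - extent[2]) / cell_size))
  origin <- c(extent[1], extent[2] + nrows * cell_size)
  g <- raster_grid(matrix(0, nrows, ncols), cell_size, origin)
  cc <- cell_centers(g)
  xm <- mean(cc$x); ym <- mean(cc$y)
  plane <- outer(cc$y - ym, cc$x - xm, function(y, x) slope[1] * x + slope[2] * y)
  vals <- mean_elevation + plane
  if (roughness_sd > 0) {
    noise <- with_seed(seed, matrix(stats::rnorm(nrows * ncols), nrows, ncols))
    field <- gaussian_smooth(noise, smooth_cells)
    s <- stats::sd(as.vector(field))
    if (s > 0) vals <- vals + field * (roughness_sd / s)
  }
  raster_grid(vals, cell_size, origin)
}

# separable Gaussian smoothing with edge renormalization
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  smooth1 <- function(mat) {
    n <- nrow(mat)
    W <- matrix(0, n, n)
    for (d in -half:half) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1 & j <= n
      W[cbind(i[ok], j[ok])] <- k[d + half + 1]
    }
    W <- W / rowSums(W)
    W %*% mat
  }
  t(smooth1(t(smooth1(m))))
}

#' Generate a synthetic orchard ground-truth table
#'
#' Trees are placed on a row grid with positional jitter. Total heights are
#' uniform over `height_range`; the trunk occupies `1 - crown_ratio` of the
#' total height and the crown is a vertical half-ellipsoid sitting on the
#' trunk top, so the analytic crown volume is `(2/3) * pi * a * b * c` with
#' horizontal semi-axes (a, b) and vertical semi-axis
#' `c = crown_ratio * total_height`.
#'
#' @param n_trees number of trees (default 20).
#' @param n_rows number of rows (default 2); a non-divisible count leaves the
#'   last row short.
#' @param spacing in-row tree spacing in meters (default 3).
#' @param row_spacing distance between rows in meters (default 4.5).
#' @param height_range `c(min, max)` total tree height in meters
#'   (default `c(2.13, 3.05)`, a mature peach range).
#' @param crown_ratio fraction of total height occupied by the crown
#'   (default 0.80).
#' @param crown_radius_range `c(min, max)` horizontal crown semi-axis range
#'   in meters (default `c(0.75, 1.15)`).
#' @param jitter positional jitter half-width in meters (default 0.15).
#' @param origin map coordinate of the first tree of the first row.
#' @param seed integer RNG seed.
#' @return a data.frame (one row per tree) with columns `tree_id`,
#'   `x_center`, `y_center`, `trunk_height`, `total_height`,
#'   `crown_radius_long`, `crown_radius_trans`, `true_crown_volume`,
#'   `row_id`.
#' @export
generate_orchard <- function(n_trees = 20, n_rows = 2, spacing = 3,
                             row_spacing = 4.5,
                             height_range = c(2.13, 3.05), crown_ratio = 0.80,
                             crown_radius_range = c(0.75, 1.15),
                             jitter = 0.15, origin = c(5, 5), seed = 1) {
  if (n_trees < 1) stop_invalid("n_trees must be >= 1")
  if (!(height_range[1] > 0 && height_range[2] > height_range[1])) {
    stop_invalid("height_range must satisfy 0 < min < max")
  }
  if (!(crown_ratio > 0 && crown_ratio <= 1)) {
    stop_invalid("crown_ratio must be in (0, 1]")
  }
  per_row <- ceiling(n_trees / n_rows)
  idx <- seq_len(n_trees) - 1L
  row_id <- idx %/% per_row
  pos <- idx %% per_row
  with_seed(seed, {
    x <- origin[1] + pos * spacing + stats::runif(n_trees, -jitter, jitter)
    y <- origin[2] + row_id * row_spacing + stats::runif(n_trees, -jitter, jitter)
    total <- stats::runif(n_trees, height_range[1], height_range[2])
    a <- stats::runif(n_trees, crown_radius_range[1], crown_radius_range[2])
    b <- stats::runif(n_trees, crown_radius_range[1], crown_radius_range[2])
  })
  trunk <- (1 - crown_ratio) * total
  cheight <- total - trunk
  data.frame(
    tree_id = seq_len(n_trees),
    x_center = x, y_center = y,
    trunk_height = trunk, total_height = total,
    crown_radius_long = a, crown_radius_trans = b,
    true_crown_volume = half_ellipsoid_volume(a, b, cheight),
    row_id = row_id)
}

#' Analytic volume of a vertical half-ellipsoid crown
#'
#' @param a,b horizontal semi-axes (m); `cc` vertical semi-axis (m).
#' @param cc vertical semi-axis in meters.
#' @return volume in cubic meters, `(2/3) * pi * a * b * cc`.
#' @export
half_ellipsoid_volume <- function(a, b, cc) (2 / 3) * pi * a * b * cc

#' Sensor view specification for point-cloud sampling
#'
#' @param inclination_deg sensor elevation angle in degrees, in (0, 90];
#'   90 is nadir (camera pointing straight down), 65 and 45 are oblique.
#' @param azimuths sensor azimuths in degrees (default every 45 degrees,
#'   emulating a double-grid mission seeing the canopy from all sides).
#' @param points_per_m2 surface sampling density (points per square meter).
#' @param noise_sd per-coordinate Gaussian noise standard deviation (m).
#' @param tilt_axis_deg azimuth of the horizontal axis of the injected
#'   whole-cloud tilt (the systematic angular bias), degrees.
#' @param tilt_angle_deg tilt magnitude in degrees, in \[0, 15\].
#' @param seed integer RNG seed.
#' @return an object of class `view_spec`.
#' @export
view_spec <- function(inclination_deg, azimuths = seq(0, 315, by = 45),
                      points_per_m2 = 80, noise_sd = 0.02,
                      tilt_axis_deg = 0, tilt_angle_deg = 0, seed = 1) {
  if (!(inclination_deg > 0 && inclination_deg <= 90)) {
    stop_invalid("inclination_deg must be in (0, 90]")
  }
  if (points_per_m2 <= 0) stop_invalid("points_per_m2 must be positive")
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (tilt_angle_deg < 0 || tilt_angle_deg > 15) {
    stop_invalid("tilt_angle_deg must be in [0, 15]")
  }
  structure(list(inclination_deg = inclination_deg, azimuths = azimuths,
                 points_per_m2 = points_per_m2, noise_sd = noise_sd,
                 tilt_axis_deg = tilt_axis_deg,
                 tilt_angle_deg = tilt_angle_deg, seed = seed),
            class = "view_spec")
}

#' Sample a view-dependent point cloud of a synthetic orchard
#'
#' Crown surfaces (vertical half-ellipsoids on trunk tops) are sampled by
#' drawing upper-hemisphere directions and mapping them to each ellipsoid;
#' a surface point is kept only if its outward normal faces the sensor
#' (positive dot product with the sensor direction) for at least one
#' azimuth. A nadir-only view therefore omits the lower crown flanks, the
#' mechanism behind the nadir-versus-oblique accuracy difference. Sparse
#' ground returns are sampled between the trees (the crown footprint shades
#' the ground). Gaussian coordinate noise is added, then the whole cloud is
#' rigidly tilted by `tilt_angle_deg` about a horizontal axis — the
#' systematic angular bias that [correct_tilt()] must remove.
#'
#' @param truth orchard truth table from [generate_orchard()].
#' @param terrain terrain `raster_grid` from [generate_terrain()].
#' @param view a [view_spec()].
#' @param ground_fraction ground-return density as a fraction of
#'   `points_per_m2` (default 0.25: ground is sampled more sparsely than
#'   canopy surfaces).
#' @return a data.frame point cloud with columns `x`, `y`, `z`, `label`
#'   ("canopy"/"ground"), `tree_id` (0 for ground), and sampling-time
#'   surface normals `nx`, `ny`, `nz`; attribute `"view"` stores the spec.
#' @export
sample_point_cloud <- function(truth, terrain, view,
                               ground_fraction = 0.25) {
  stopifnot(inherits(view, "view_spec"))
  if (nrow(truth) == 0) {
    warning("empty truth table: returning empty cloud")
    out <- data.frame(x = numeric(), y = numeric(), z = numeric(),
                      label = character(), tree_id = integer(),
                      nx = numeric(), ny = numeric(), nz = numeric())
    attr(out, "view") <- view
    return(out)
  }
  ext <- grid_extent(terrain)
  inside <- truth$x_center >= ext[1] & truth$x_center <= ext[3] &
    truth$y_center >= ext[2] & truth$y_center <= ext[4]
  if (!all(inside)) stop_invalid("trees lie outside the terrain extent")

  elev <- view$inclination_deg * pi / 180
  az <- view$azimuths * pi / 180
  # unit vectors pointing from the surface toward the sensor
  sensors <- cbind(cos(az) * cos(elev), sin(az) * cos(elev), sin(elev))

  cloud <- with_seed(view$seed, {
    parts <- lapply(seq_len(nrow(truth)), function(i) {
      tr <- truth[i, ]
      a <- tr$crown_radius_long; b <- tr$crown_radius_trans
      cc <- tr$total_height - tr$trunk_height
      # Thomsen approximation of the ellipsoid surface area, halved
      p <- 1.6075
      area <- 2 * pi * (((a * b)^p + (a * cc)^p + (b * cc)^p) / 3)^(1 / p)
      n <- max(8L, round(view$points_per_m2 * area))
      u <- matrix(stats::rnorm(3 * n), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      u[, 3] <- abs(u[, 3]) # upper hemisphere
      px <- a * u[, 1]; py <- b * u[, 2]; pz <- cc * u[, 3]
      nv <- cbind(u[, 1] / a, u[, 2] / b, u[, 3] / cc)
      nv <- nv / sqrt(rowSums(nv^2))
      vis <- apply(nv %*% t(sensors) > 0, 1, any)
      z0 <- sample_bilinear(terrain, tr$x_center, tr$y_center) + tr$trunk_height
      data.frame(x = tr$x_center + px[vis], y = tr$y_center + py[vis],
                 z = z0 + pz[vis], label = "canopy", tree_id = tr$tree_id,
                 nx = nv[vis, 1], ny = nv[vis, 2], nz = nv[vis, 3])
    })
    # sparse ground returns between the trees
    area_ext <- (ext[3] - ext[1]) * (ext[4] - ext[2])
    ng <- round(ground_fraction * view$points_per_m2 * area_ext)
    gx <- stats::runif(ng, ext[1], ext[3])
    gy <- stats::runif(ng, ext[2], ext[4])
    shaded <- rep(FALSE, ng)
    for (i in seq_len(nrow(truth))) {
      tr <- truth[i, ]
      shaded <- shaded | ((gx - tr$x_center) / tr$crown_radius_long)^2 +
        ((gy - tr$y_center) / tr$crown_radius_trans)^2 < 1
    }
    gx <- gx[!shaded]; gy <- gy[!shaded]
    ground <- data.frame(x = gx, y = gy, z = sample_bilinear(terrain, gx, gy),
                         label = "ground", tree_id = 0L,
                         nx = 0, ny = 0, nz = 1)
    out <- rbind(do.call(rbind, parts), ground)
    if (view$noise_sd > 0) {
      m <- nrow(out)
      out$x <- out$x + stats::rnorm(m, 0, view$noise_sd)
      out$y <- out$y + stats::rnorm(m, 0, view$noise_sd)
      out$z <- out$z + stats::rnorm(m, 0, view$noise_sd)
    }
    out
  })
  if (view$tilt_angle_deg > 0) {
    cloud <- apply_tilt(cloud, view$tilt_axis_deg, view$tilt_angle_deg)
  }
  rownames(cloud) <- NULL
  attr(cloud, "view") <- view
  cloud
}

#' Rigidly tilt a point cloud about a horizontal axis
#'
#' Rotates the cloud by `angle_deg` about the horizontal axis with azimuth
#' `axis_deg`, through the cloud centroid (or a supplied center). Used to
#' inject the systematic angular bias into synthetic clouds.
#'
#' @param cloud point-cloud data.frame with `x`, `y`, `z`.
#' @param axis_deg azimuth of the rotation axis in degrees.
#' @param angle_deg rotation angle in degrees.
#' @param center optional length-3 rotation center (default: centroid).
#' @return the tilted cloud (other columns preserved).
#' @export
apply_tilt <- function(cloud, axis_deg, angle_deg, center = NULL) {
  ax <- c(cos(axis_deg * pi / 180), sin(axis_deg * pi / 180), 0)
  R <- rotation_matrix(ax, angle_deg * pi / 180)
  P <- as.matrix(cloud[, c("x", "y", "z")])
  if (is.null(center)) center <- colMeans(P)
  Q <- sweep(sweep(P, 2, center) %*% t(R), 2, center, `+`)
  cloud$x <- Q[, 1]; cloud$y <- Q[, 2]; cloud$z <- Q[, 3]
  cloud
}

#' Rasterize a point cloud into a digital surface model
#'
#' Each cell takes the maximum z of the points falling in it (half-open
#' cell membership); empty cells are filled with the value of the nearest
#' non-empty cell.
#'
#' @param cloud point-cloud data.frame with `x`, `y`, `z`.
#' @param cell_size cell edge in meters.
#' @param extent `c(xmin, ymin, xmax, ymax)`.
#' @return a `raster_grid` DSM.
#' @export
rasterize_dsm <- function(cloud, cell_size, extent) {
  if (nrow(cloud) == 0) stop_invalid("empty cloud")
  ncols <- max(1L, ceiling((extent[3] - extent[1]) / cell_size))
  nrows <- max(1L, ceiling((extent[4] - extent[2]) / cell_size))
  origin <- c(extent[1], extent[2] + nrows * cell_size)
  g <- raster_grid(matrix(NA_real_, nrows, ncols), cell_size, origin)
  ij <- cell_index(g, cloud$x, cloud$y)
  ok <- !is.na(ij$row)
  if (!any(ok)) {
    warning("extent covers no point: returning all-nodata raster")
    g$values[] <- g$nodata
    return(g)
  }
  idx <- (ij$col[ok] - 1L) * nrows + ij$row[ok]
  z <- cloud$z[ok]
  o <- order(z) # ascending: the last write into each cell is its max
  m <- g$values
  m[idx[o]] <- z[o]
  empty <- which(is.na(m))
  if (length(empty)) {
    filled <- which(!is.na(m))
    cc <- cell_centers(g)
    coord <- function(lin) {
      r <- (lin - 1L) %% nrows + 1L
      cl <- (lin - 1L) %/% nrows + 1L
      cbind(cc$x[cl], cc$y[r])
    }
    nn <- FNN::get.knnx(coord(filled), coord(empty), k = 1)$nn.index
    m[empty] <- m[filled[nn]]
  }
  g$values <- m
  g
}

#' Write a synthetic fixture set to disk
#'
#' Writes ASCII-grid rasters, XYZ CSV point clouds (one per view plus the
#' integrated union), the ground-truth CSV, and a YAML manifest listing
#' everything. All formats are plain text and round-trip through the
#' package readers.
#'
#' @param outdir output directory (created if missing).
#' @param truth orchard truth table.
#' @param dsm,dtm `raster_grid` objects.
#' @param clouds named list of point-cloud data.frames; a cloud named
#'   `"integrated"` is written like the rest.
#' @return the manifest (named list of relative file paths), invisibly.
#' @export
write_fixture_set <- function(outdir, truth, dsm, dtm, clouds) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop_invalid("cannot create output directory: ", outdir)
  manifest <- list(truth = "truth.csv", dsm = "dsm.asc", dtm = "dtm.asc",
                   clouds = list())
  utils::write.csv(truth, file.path(outdir, "truth.csv"), row.names = FALSE)
  write_ascii_grid(dsm, file.path(outdir, "dsm.asc"))
  write_ascii_grid(dtm, file.path(outdir, "dtm.asc"))
  for (nm in names(clouds)) {
    f <- sprintf("cloud_%s.csv", nm)
    write_xyz_csv(clouds[[nm]], file.path(outdir, f))
    manifest$clouds[[nm]] <- f
  }
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(manifest)
}

#' Write a point cloud as XYZ CSV
#'
#' @param cloud data.frame with at least `x`, `y`, `z`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_xyz_csv <- function(cloud, path) {
  utils::write.csv(cloud[, c("x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

#' Read an XYZ CSV point cloud
#'
#' @param path CSV with header `x,y,z` (extra columns preserved).
#' @return a point-cloud data.frame.
#' @export
read_xyz_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(d))) {
    stop_invalid("point-cloud CSV must have x,y,z columns")
  }
  d
}
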