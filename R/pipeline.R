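#' Default pipeline configuration
#'
#' All tunables of the four stages with their documented defaults: a 20-tree
#' two-row orchard with heights on 2.13–3.05 m, 0.80 crown ratio, 0.05 m
#' raster cells, 0.02 m coordinate noise and a 3 degree angular bias;
#' sensor views at 45/65/90 degrees plus their integration; 0.5 m canopy
#' reclassification cut; IDW power 2 with 12 neighbours and 100 ground
#' samples; statistical outlier filter k = 8, 2 sd; 0.1 m crown voxels and
#' a 0.20 trunk cut; 0.03 m down-sampling for the terrestrial-LiDAR preset.
#'
#' @param seed integer master seed.
#' @return a nested configuration list, YAML-serializable.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(
      enabled = TRUE,
      n_trees = 20, n_rows = 2, spacing = 3, row_spacing = 4.5,
      height_range = c(2.13, 3.05), crown_ratio = 0.80,
      crown_radius_range = c(0.75, 1.15),
      cell_size = 0.05, mean_elevation = 700, slope = 0.01,
      roughness_sd = 0.05, extent_margin = 3,
      points_per_m2 = 80, noise_sd = 0.02,
      tilt_axis_deg = 0, tilt_angle_deg = 3,
      inclinations = c(45, 65, 90),
      lidar = list(enabled = TRUE, points_per_m2 = 200,
                   inclinations = c(30, 75), n_trees = 17)),
    inputs = list(dsm = NULL, dtm = NULL, clouds = NULL, extents = NULL,
                  reference = NULL),
    chm = list(t1 = TRUE, t2 = TRUE, height_threshold = 0.5,
               boundary_kinds = c("polygon", "box", "circle"),
               crown_ratio = 0.80, idw_power = 2, idw_k = 12,
               n_ground_points = 100),
    cloud = list(enabled = TRUE, ground_quantile = 0.1, filter_k = 8,
                 filter_sd_mult = 2, voxel_size = 0.1, trunk_fraction = 0.20,
                 lidar_downsample = 0.03),
    report = list(excluded_ids = integer(0)))
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()] values (recursive merge).
#'
#' @param path YAML file path.
#' @param seed seed used when the file does not set one.
#' @return a configuration list.
#' @export
read_config <- function(path, seed = 1) {
  user <- yaml::read_yaml(path)
  merge_config(default_config(seed), user)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Simulate the full set of synthetic orchard data products
#'
#' Generates terrain and ground truth, samples one point cloud per sensor
#' inclination plus their integrated union, rasterizes per-dataset DSMs from
#' the level clouds (photogrammetric products are georeferenced, so the
#' angular bias is injected only into the point-cloud copies), and builds
#' per-tree segmentation extents midway to the neighbouring trees.
#'
#' @param cfg configuration list (the `simulate` part of [default_config()]).
#' @param seed integer master seed.
#' @return list with `truth`, `terrain`, `dsm` (named list), `clouds`
#'   (named list, tilted), `extents`, `reference`.
#' @export
simulate_orchard_products <- function(cfg, seed = 1) {
  truth <- generate_orchard(
    n_trees = cfg$n_trees, n_rows = cfg$n_rows, spacing = cfg$spacing,
    row_spacing = cfg$row_spacing, height_range = cfg$height_range,
    crown_ratio = cfg$crown_ratio,
    crown_radius_range = cfg$crown_radius_range, seed = seed)
  m <- cfg$extent_margin
  extent <- extent_rect(min(truth$x_center) - m, min(truth$y_center) - m,
                        max(truth$x_center) + m, max(truth$y_center) + m)
  terrain <- generate_terrain(extent, cfg$cell_size,
                              mean_elevation = cfg$mean_elevation,
                              slope = cfg$slope,
                              roughness_sd = cfg$roughness_sd,
                              seed = seed + 1000L)
  tilt_center <- c(mean(extent[c(1, 3)]), mean(extent[c(2, 4)]),
                   cfg$mean_elevation)
  level <- list()
  for (i in seq_along(cfg$inclinations)) {
    inc <- cfg$inclinations[i]
    vs <- view_spec(inc, points_per_m2 = cfg$points_per_m2,
                    noise_sd = cfg$noise_sd, tilt_angle_deg = 0,
                    seed = seed + 10L * i)
    level[[as.character(inc)]] <- sample_point_cloud(truth, terrain, vs)
  }
  level[["integrated"]] <- do.call(rbind, c(level, list(make.row.names = FALSE)))
  dsm <- lapply(level, rasterize_dsm, cell_size = cfg$cell_size,
                extent = extent)
  clouds <- lapply(level, function(cl) {
    if (cfg$tilt_angle_deg > 0) {
      apply_tilt(cl, cfg$tilt_axis_deg, cfg$tilt_angle_deg,
                 center = tilt_center)
    } else cl
  })
  if (isTRUE(cfg$lidar$enabled)) {
    sub <- truth[seq_len(min(cfg$lidar$n_trees, nrow(truth))), ]
    li <- list()
    for (i in seq_along(cfg$lidar$inclinations)) {
      vs <- view_spec(cfg$lidar$inclinations[i],
                      points_per_m2 = cfg$lidar$points_per_m2,
                      noise_sd = cfg$noise_sd, tilt_angle_deg = 0,
                      seed = seed + 100L + i)
      li[[i]] <- sample_point_cloud(sub, terrain, vs)
    }
    li <- do.call(rbind, li)
    if (cfg$tilt_angle_deg > 0) {
      li <- apply_tilt(li, cfg$tilt_axis_deg, cfg$tilt_angle_deg,
                       center = tilt_center)
    }
    attr(li, "tree_ids") <- sub$tree_id
    clouds[["lidar"]] <- li
  }
  half_x <- pmin(truth$crown_radius_long + 0.35, cfg$spacing / 2 - 0.05)
  half_y <- pmin(truth$crown_radius_trans + 0.35, cfg$row_spacing / 2 - 0.05)
  extents <- data.frame(tree_id = truth$tree_id,
                        xmin = truth$x_center - half_x,
                        ymin = truth$y_center - half_y,
                        xmax = truth$x_center + half_x,
                        ymax = truth$y_center + half_y)
  reference <- data.frame(tree_id = truth$tree_id,
                          height_m = truth$total_height,
                          volume_m3 = truth$true_crown_volume)
  list(truth = truth, terrain = terrain, dsm = dsm, clouds = clouds,
       extents = extents, reference = reference)
}

#' Extract raster-based traits (T1/T2 canopy height models)
#'
#' Builds the CHM either from a delivered terrain model (T1) or from an
#' IDW-interpolated terrain reconstructed from sampled ground points (T2),
#' reclassifies it into a canopy mask, delineates each tree in the requested
#' boundary geometries, and records the zonal maximum height and the
#' pyramid crown volume per tree.
#'
#' @param dsm digital surface model `raster_grid`.
#' @param dtm digital terrain model `raster_grid` (T1), or `NULL` to
#'   reconstruct one by ground sampling (T2).
#' @param extents per-tree extent table (`tree_id, xmin, ymin, xmax, ymax`).
#' @param dataset dataset label carried into the records (e.g. "45",
#'   "integrated").
#' @param cfg the `chm` part of [default_config()].
#' @param seed seed for ground-point placement (T2).
#' @return data.frame of trait records
#'   (`tree_id, dataset, method, boundary, height_m, volume_m3`).
#' @export
extract_traits_raster <- function(dsm, dtm, extents, dataset, cfg, seed = 1) {
  method <- if (is.null(dtm)) "T2" else "T1"
  if (is.null(dtm)) {
    # canopy mask from a provisional CHM against a flat reference level so
    # that ground samples avoid the trees; the reference is the DSM minimum
    prov <- raster_grid(dsm$values - min(dsm$values[dsm$values != dsm$nodata]),
                        dsm$cell_size, dsm$origin, dsm$nodata)
    avoid <- reclassify_canopy(prov, cfg$height_threshold)
    gp <- stratified_ground_points(grid_extent(dsm), n = cfg$n_ground_points,
                                   seed = seed, avoid_mask = avoid)
    dtm <- sample_dtm_idw(dsm, gp, power = cfg$idw_power,
                          k_neighbors = cfg$idw_k)
  }
  chm <- compute_chm(dsm, dtm)
  mask <- reclassify_canopy(chm, cfg$height_threshold)
  out <- list()
  for (kind in cfg$boundary_kinds) {
    bounds <- extract_boundaries(mask, extents, kind = kind)
    for (b in bounds) {
      h <- zonal_max_height(chm, b)
      v <- pyramid_crown_volume(b, h, crown_ratio = cfg$crown_ratio)
      out[[length(out) + 1L]] <- data.frame(
        tree_id = b$tree_id, dataset = dataset, method = method,
        boundary = kind, height_m = h, volume_m3 = v)
    }
  }
  do.call(rbind, out)
}

#' Extract point-cloud traits (UAV or LiDAR path)
#'
#' Levels the cloud ([correct_tilt()]), removes statistical outliers
#' ([filter_cloud()]; the LiDAR preset also voxel down-samples), segments
#' each tree by its extent, and records the height `Zmax - Zmin`, the
#' tetrahedral hull crown volume and the voxel-grid crown volume.
#'
#' @param cloud input point-cloud data.frame.
#' @param extents per-tree extent table.
#' @param dataset dataset label (e.g. "45", "integrated", "lidar").
#' @param cfg the `cloud` part of [default_config()].
#' @param method record label: "pointcloud" reports the hull volume,
#'   "lidar" the voxel-grid volume.
#' @param min_height trees with an apparent height below this are treated as
#'   absent from the cloud and skipped (default 1 m): an extent containing
#'   only ground returns yields a spurious near-zero height, not a tree.
#' @return data.frame of trait records, plus `voxel_volume_m3` and
#'   `hull_volume_m3` columns for both estimators.
#' @export
extract_traits_cloud <- function(cloud, extents, dataset, cfg,
                                 method = "pointcloud", min_height = 1) {
  ids <- attr(cloud, "tree_ids")
  if (!is.null(ids)) extents <- extents[extents$tree_id %in% ids, ]
  cl <- correct_tilt(cloud, ground_quantile = cfg$ground_quantile)
  cl <- filter_cloud(cl, k = cfg$filter_k, sd_mult = cfg$filter_sd_mult,
                     voxel_downsample = if (method == "lidar")
                       cfg$lidar_downsample else NULL)
  out <- list()
  for (t in seq_len(nrow(extents))) {
    te <- extents[t, ]
    tc <- tryCatch(
      segment_tree(cl, extent = c(te$xmin, te$ymin, te$xmax, te$ymax),
                   tree_id = te$tree_id),
      error = function(e) NULL)
    if (is.null(tc) || nrow(tc) < 4) next
    h <- tree_height(tc)
    if (h < min_height) next
    crown <- delineate_crown(tc, trunk_fraction = cfg$trunk_fraction)
    vv <- voxel_grid_volume(crown, voxel_size = cfg$voxel_size)
    hv <- tryCatch(hull_volume(crown), error = function(e) NA_real_)
    out[[length(out) + 1L]] <- data.frame(
      tree_id = te$tree_id, dataset = dataset, method = method,
      boundary = NA_character_, height_m = h,
      volume_m3 = if (method == "lidar") vv else hv,
      voxel_volume_m3 = vv, hull_volume_m3 = hv)
  }
  do.call(rbind, out)
}

#' Run the full trait-extraction pipeline
#'
#' Orchestrates simulate (optional) -> CHM (T1 and/or T2) -> point cloud ->
#' report: the complete grid of methods x datasets x boundary geometries,
#' correlated against the ground reference. Writes trait records,
#' correlation and summary CSVs, figures, the configuration and a manifest
#' into `outdir`.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @param outdir output directory (default `"orchard-run"`).
#' @param quiet suppress stage messages.
#' @return list with `status` (0 on success), `outdir`, `traits`,
#'   `reference`, `correlations`, `summaries` and `height_matrices`
#'   (per-method correlation matrices across datasets), invisibly.
#' @export
run_pipeline <- function(config = default_config(), outdir = "orchard-run",
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  if (isTRUE(config$simulate$enabled)) {
    say("stage simulate: generating synthetic orchard (seed %d)", config$seed)
    sim <- simulate_orchard_products(config$simulate, seed = config$seed)
    say("  %d trees, %d datasets, %s cloud points total",
        nrow(sim$truth), length(sim$clouds),
        format(sum(vapply(sim$clouds, nrow, 0L)), big.mark = ","))
    fixdir <- file.path(outdir, "fixtures")
    write_fixture_set(fixdir, sim$truth, sim$dsm[["integrated"]],
                      sim$terrain, sim$clouds)
    utils::write.csv(sim$extents, file.path(fixdir, "extents.csv"),
                     row.names = FALSE)
    utils::write.csv(sim$reference, file.path(fixdir, "reference.csv"),
                     row.names = FALSE)
    dsm <- sim$dsm; dtm <- sim$terrain; clouds <- sim$clouds
    extents <- sim$extents; reference <- sim$reference
  } else {
    say("stage load: reading inputs")
    inp <- config$inputs
    dsm <- lapply(inp$dsm, read_ascii_grid)
    dtm <- if (!is.null(inp$dtm)) read_ascii_grid(inp$dtm) else NULL
    clouds <- lapply(inp$clouds, read_xyz_csv)
    extents <- utils::read.csv(inp$extents)
    reference <- utils::read.csv(inp$reference)
  }

  traits <- list()
  raster_sets <- setdiff(names(dsm), "lidar")
  for (ds in raster_sets) {
    if (isTRUE(config$chm$t1) && !is.null(dtm)) {
      say("stage chm: T1 on dataset %s", ds)
      traits[[length(traits) + 1L]] <-
        extract_traits_raster(dsm[[ds]], dtm, extents, ds, config$chm)
    }
    if (isTRUE(config$chm$t2)) {
      say("stage chm: T2 on dataset %s", ds)
      traits[[length(traits) + 1L]] <-
        extract_traits_raster(dsm[[ds]], NULL, extents, ds, config$chm,
                              seed = config$seed + 17L)
    }
  }
  if (isTRUE(config$cloud$enabled)) {
    for (ds in names(clouds)) {
      method <- if (ds == "lidar") "lidar" else "pointcloud"
      say("stage cloud: %s on dataset %s (%d points)", method, ds,
          nrow(clouds[[ds]]))
      traits[[length(traits) + 1L]] <-
        extract_traits_cloud(clouds[[ds]], extents, ds, config$cloud,
                             method = method)
    }
  }
  traits <- do.call(rbind, lapply(traits, function(d) {
    d[, c("tree_id", "dataset", "method", "boundary", "height_m",
          "volume_m3")]
  }))
  utils::write.csv(traits, file.path(outdir, "traits.csv"), row.names = FALSE)

  say("stage report: correlations against ground reference")
  rep_out <- summarize_traits(traits, reference,
                              excluded_ids = config$report$excluded_ids)
  paired <- rep_out$paired
  files <- build_report(rep_out$correlations, rep_out$summaries, paired,
                        outdir)

  yaml::write_yaml(config, file.path(outdir, "config.yaml"))
  manifest <- list(
    package = as.character(utils::packageVersion("orchardtraits")),
    config_md5 = unname(tools::md5sum(file.path(outdir, "config.yaml"))),
    seed = config$seed,
    n_trait_records = nrow(traits),
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    files = basename(c(files, file.path(outdir, "traits.csv"))))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  say("done in %.1f s", manifest$runtime_s)

  invisible(list(status = 0L, outdir = outdir, traits = traits,
                 reference = reference,
                 correlations = rep_out$correlations,
                 summaries = rep_out$summaries,
                 height_matrices = rep_out$height_matrices))
}

#' Correlate trait records against a ground-reference table
#'
#' For every method x dataset x boundary combination, pairs the estimates
#' with the reference (minus excluded trees) and computes the Pearson
#' correlation with stars and the linear fit, for height and crown volume;
#' also builds, per method, the full correlation matrix of tree height
#' across datasets (reference included).
#'
#' @param traits trait-record data.frame.
#' @param reference data.frame `tree_id, height_m, volume_m3`.
#' @param excluded_ids tree ids excluded from all pairings.
#' @return list with `correlations`, `summaries`, `paired`,
#'   `height_matrices`.
#' @export
summarize_traits <- function(traits, reference, excluded_ids = integer(0)) {
  combos <- unique(traits[, c("method", "dataset", "boundary")])
  cors <- list(); sums <- list(); paired <- list()
  sums[[1]] <- summarize_distribution(reference$height_m, "ground height (m)")
  sums[[2]] <- summarize_distribution(reference$volume_m3, "ground volume (m3)")
  for (i in seq_len(nrow(combos))) {
    cb <- combos[i, ]
    sel <- traits$method == cb$method & traits$dataset == cb$dataset &
      (is.na(cb$boundary) | traits$boundary %in% cb$boundary)
    sub <- traits[sel, ]
    jd <- exclude_outliers(sub, reference, excluded_ids)
    lab <- paste0(cb$method, "-", cb$dataset,
                  ifelse(is.na(cb$boundary), "", paste0("-", cb$boundary)))
    if (nrow(jd) >= 3) {
      cors[[length(cors) + 1L]] <- cbind(
        trait = "height",
        pearson_with_stars(jd$height_m_ref, jd$height_m_est,
                           paste(lab, "vs ground")))
      if (all(is.finite(jd$volume_m3_est))) {
        cors[[length(cors) + 1L]] <- cbind(
          trait = "volume",
          pearson_with_stars(jd$volume_m3_ref, jd$volume_m3_est,
                             paste(lab, "vs ground")))
      }
      paired[[length(paired) + 1L]] <- data.frame(
        pair = lab, reference = jd$height_m_ref, estimate = jd$height_m_est)
    }
    sums[[length(sums) + 1L]] <- summarize_distribution(
      sub$height_m, paste(lab, "height (m)"))
    sums[[length(sums) + 1L]] <- summarize_distribution(
      sub$volume_m3, paste(lab, "volume (m3)"))
  }
  height_matrices <- list()
  for (mth in unique(traits$method)) {
    sub <- traits[traits$method == mth, ]
    # heights do not depend on the boundary kind; keep one kind per dataset
    first_kind <- sub$boundary[1]
    if (!is.na(first_kind)) sub <- sub[sub$boundary == first_kind, ]
    keep_ids <- setdiff(intersect(sub$tree_id, reference$tree_id),
                        excluded_ids)
    vecs <- list()
    complete <- TRUE
    for (ds in unique(sub$dataset)) {
      v <- sub[sub$dataset == ds, ]
      v <- stats::setNames(v$height_m, v$tree_id)
      if (!all(as.character(keep_ids) %in% names(v))) { complete <- FALSE; next }
      vecs[[ds]] <- v[as.character(keep_ids)]
    }
    if (length(vecs) >= 1) {
      ref_v <- stats::setNames(reference$height_m, reference$tree_id)
      height_matrices[[mth]] <- correlation_matrix(
        vecs, ref_v[as.character(keep_ids)])
    }
  }
  list(correlations = do.call(rbind, cors),
       summaries = do.call(rbind, sums),
       paired = do.call(rbind, paired),
       height_matrices = height_matrices)
}
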