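test_that("tilt correction recovers an injected angular bias", {
  terr <- flat_terrain(c(0, 0, 30, 15), cell = 0.1)
  tr <- generate_orchard(n_trees = 6, n_rows = 2, origin = c(6, 5), seed = 3)
  vs <- view_spec(45, points_per_m2 = 60, noise_sd = 0.02,
                  tilt_axis_deg = 30, tilt_angle_deg = 3, seed = 6)
  cl <- sample_point_cloud(tr, terr, vs)
  lev <- correct_tilt(cl)
  expect_lt(abs(attr(lev, "tilt_deg") - 3), 0.1)
  # pure rotation: pairwise distances preserved
  idx <- seq(1, nrow(cl), length.out = 50)
  d0 <- dist(as.matrix(cl[idx, c("x", "y", "z")]))
  d1 <- dist(as.matrix(lev[idx, c("x", "y", "z")]))
  expect_lt(max(abs(d1 - d0) / pmax(d0, 1e-12)), 1e-9)
  # the ground is flatter after correction than before
  sd_ground <- function(d) sd(d$z[d$label == "ground"])
  expect_lte(sd_ground(lev), sd_ground(cl))
})

test_that("an already level cloud passes through tilt correction unchanged", {
  terr <- flat_terrain(c(0, 0, 30, 15), cell = 0.1)
  tr <- generate_orchard(n_trees = 6, n_rows = 2, origin = c(6, 5), seed = 3)
  vs <- view_spec(45, points_per_m2 = 60, noise_sd = 0, seed = 6)
  cl <- sample_point_cloud(tr, terr, vs)
  lev <- correct_tilt(cl)
  expect_lt(attr(lev, "tilt_deg"), 1e-4)
  expect_equal(lev$z, cl$z, tolerance = 1e-6)
  expect_error(correct_tilt(cl[1:5, ]), "at least 10")
})

test_that("statistical outlier removal drops isolated points only", {
  withr::with_seed(10, {
    cluster <- data.frame(x = rnorm(300, sd = 0.3), y = rnorm(300, sd = 0.3),
                          z = rnorm(300, sd = 0.3))
  })
  cl <- rbind(cluster, data.frame(x = 100, y = 100, z = 100))
  f <- filter_cloud(cl, k = 8, sd_mult = 2)
  expect_equal(nrow(f), 300)
  expect_true(all(f$x < 50))
  # sd_mult = Inf is the identity
  expect_equal(nrow(filter_cloud(cl, k = 8, sd_mult = Inf)), 301)
  # clouds smaller than k + 1 are returned unchanged with a warning
  expect_warning(f2 <- filter_cloud(cl[1:4, ], k = 8), "unchanged")
  expect_equal(nrow(f2), 4)
})

test_that("voxel down-sampling keeps one centroid per occupied voxel", {
  # two points per 0.05 m voxel -> count halves
  base <- expand.grid(x = seq(0.01, 0.96, by = 0.05),
                      y = seq(0.01, 0.96, by = 0.05), z = 0.01)
  cl <- rbind(base, transform(base, z = 0.03)) # same voxel, different z
  f <- filter_cloud(cl, k = 1, sd_mult = Inf, voxel_downsample = 0.05)
  expect_equal(nrow(f), nrow(base))
  expect_equal(sort(f$x), sort(base$x), tolerance = 1e-12)
})

test_that("tree segmentation uses half-open extents", {
  cl <- data.frame(x = c(0, 0.5, 1, 1.5, 2), y = rep(0.5, 5), z = 1:5)
  seg <- segment_tree(cl, extent = c(0, 0, 2, 1))
  expect_equal(seg$x, c(0, 0.5, 1, 1.5)) # max edge excluded, min included
  # trees 3 m apart with 2 m extents share nothing
  two <- data.frame(x = c(rep(1, 10), rep(4, 10)),
                    y = 0.5, z = rep(1:10, 2))
  a <- segment_tree(two, center = c(1, 0.5), size = c(2, 2))
  b <- segment_tree(two, center = c(4, 0.5), size = c(2, 2))
  expect_equal(nrow(a) + nrow(b), nrow(two))
  expect_error(segment_tree(cl, extent = c(50, 50, 60, 60), tree_id = 3),
               "tree 3")
})

test_that("height is the z range and crown delineation cuts the trunk", {
  cl <- data.frame(x = 0, y = 0, z = c(700.0, 702.7))
  expect_equal(tree_height(cl), 2.7)
  # a point inside the range leaves the height unchanged
  expect_equal(tree_height(rbind(cl, data.frame(x = 0, y = 0, z = 701))), 2.7)
  expect_error(tree_height(cl[1, ]), "at least 2")
  tc <- data.frame(x = 0, y = 0, z = c(700, 700.5, 700.61, 701.5, 703))
  crown <- delineate_crown(tc, trunk_fraction = 0.2) # cut at 700.6
  expect_true(all(crown$z >= 700.6))
  expect_equal(nrow(crown), 3)
  expect_equal(nrow(delineate_crown(tc, trunk_fraction = 0)), 5)
})

test_that("voxel-grid volume counts occupied half-open voxels", {
  one <- data.frame(x = 0.02, y = 0.03, z = 0.04)
  expect_equal(voxel_grid_volume(one, 0.1), 0.1^3)
  # volume is always an integer multiple of voxel^3
  sol <- ellipsoid_solid(20000, seed = 2)
  v <- voxel_grid_volume(sol, 0.07)
  expect_equal(v / 0.07^3, round(v / 0.07^3), tolerance = 1e-9)
})

test_that("hull volume matches closed forms and brackets sampled solids", {
  cube <- as.data.frame(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  expect_equal(hull_volume(cube), 1.0, tolerance = 1e-14)
  tet <- data.frame(x = c(0, 1, 0.5, 0.5), y = c(0, 0, sqrt(3) / 2, sqrt(3) / 6),
                    z = c(0, 0, 0, sqrt(2 / 3)))
  expect_equal(hull_volume(tet), 1 / (6 * sqrt(2)), tolerance = 1e-12)
  # interior points never change the hull
  withr::with_seed(3, {
    inner <- data.frame(x = runif(200, 0.1, 0.9), y = runif(200, 0.1, 0.9),
                        z = runif(200, 0.1, 0.9))
  })
  expect_equal(hull_volume(rbind(cube, inner)), 1.0, tolerance = 1e-12)
  expect_error(hull_volume(cube[1:3, ]), "at least 4")
  flat <- data.frame(x = runif(10), y = runif(10), z = 0)
  expect_error(hull_volume(flat), "coplanar")
})

test_that("hull and voxel volumes bracket the analytic ellipsoid volume", {
  vol <- 4 / 3 * pi * 1 * 0.8 * 0.6
  surf <- ellipsoid_surface(3000, seed = 4)
  hv <- hull_volume(surf)
  expect_lt(hv, vol)           # inscribed hull: always from below
  expect_gt(hv, vol * 0.97)
  sol <- ellipsoid_solid(60000, seed = 5)
  voxel <- 0.1
  vv <- voxel_grid_volume(sol, voxel)
  # hull <= analytic <= voxel + one voxel shell
  shell <- 9.7 * voxel # ellipsoid surface area x voxel size, generous
  expect_lte(hv, vol)
  expect_lte(vol, vv + shell)
  expect_gte(vv + shell, vol)
})

test_that("traits are invariant under horizontal translation", {
  sol <- ellipsoid_solid(20000, seed = 6)
  shifted <- transform(sol, x = x + 137.5, y = y - 42.25)
  expect_equal(tree_height(shifted), tree_height(sol), tolerance = 1e-9)
  expect_equal(hull_volume(shifted), hull_volume(sol), tolerance = 1e-6)
  v0 <- voxel_grid_volume(sol, 0.1)
  v1 <- voxel_grid_volume(shifted, 0.1)
  # voxel grids re-anchor: counts may differ by at most a surface shell
  expect_lt(abs(v1 - v0) / v0, 0.15)
})
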