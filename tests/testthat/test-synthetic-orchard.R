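test_that("terrain generator honours plane parameters exactly", {
  g <- generate_terrain(c(0, 0, 200, 10), 1, mean_elevation = 700,
                        slope = 0, roughness_sd = 0, seed = 1)
  expect_true(all(g$values == 700))
  # linear plane: cells 100 m apart in x differ by exactly 1 m at slope 0.01
  g2 <- generate_terrain(c(0, 0, 200, 10), 1, slope = 0.01,
                         roughness_sd = 0, seed = 1)
  cc <- cell_centers(g2)
  j <- which(cc$x == 50.5); j2 <- which(cc$x == 150.5)
  expect_equal(g2$values[1, j2] - g2$values[1, j], 1.0)
  # determinism
  a <- generate_terrain(c(0, 0, 20, 10), 0.5, roughness_sd = 0.1, seed = 9)
  b <- generate_terrain(c(0, 0, 20, 10), 0.5, roughness_sd = 0.1, seed = 9)
  expect_identical(a$values, b$values)
  expect_error(generate_terrain(c(0, 0, 10, 10), cell_size = -1), "positive")
})

test_that("orchard truth has the layout and invariants of the field data", {
  tr <- generate_orchard(n_trees = 20, n_rows = 2, seed = 4)
  expect_equal(nrow(tr), 20)
  expect_setequal(unique(tr$row_id), c(0, 1))
  expect_equal(as.integer(table(tr$row_id)), c(10L, 10L))
  expect_true(all(tr$total_height >= 2.13 & tr$total_height <= 3.05))
  expect_true(all(tr$total_height > tr$trunk_height))
  expect_true(all(tr$trunk_height > 0))
  expect_true(all(tr$true_crown_volume > 0))
  expect_false(any(duplicated(tr$tree_id)))
  # trunk = (1 - crown_ratio) * total
  expect_equal(tr$trunk_height, 0.2 * tr$total_height, tolerance = 1e-12)
  # analytic crown volume matches the half-ellipsoid closed form
  expect_equal(tr$true_crown_volume,
               2 / 3 * pi * tr$crown_radius_long * tr$crown_radius_trans *
                 (tr$total_height - tr$trunk_height),
               tolerance = 1e-9)
  # a non-divisible tree count leaves the last row short, without error
  tr2 <- generate_orchard(n_trees = 7, n_rows = 2, seed = 1)
  expect_equal(as.integer(table(tr2$row_id)), c(4L, 3L))
})

test_that("view sampling recovers tree height and respects visibility", {
  terr <- flat_terrain()
  tr <- generate_orchard(n_trees = 1, n_rows = 1, origin = c(10, 6), seed = 2)
  vs <- view_spec(90, points_per_m2 = 300, noise_sd = 0, seed = 5)
  cl <- sample_point_cloud(tr, terr, vs)
  # nadir cloud of one tree: top minus ground equals the true height
  est <- max(cl$z) - min(cl$z[cl$label == "ground"])
  expect_equal(est, tr$total_height, tolerance = 0.02)
  # no normal faces away from every sensor direction (visibility test)
  canopy <- cl[cl$label == "canopy", ]
  expect_true(all(canopy$nz > 0)) # nadir: only upward-facing surfaces
})

test_that("single-view clouds are subsets of the integrated union and flank
           coverage grows with obliqueness", {
  terr <- flat_terrain()
  tr <- generate_orchard(n_trees = 1, n_rows = 1, origin = c(10, 6), seed = 2)
  counts <- sapply(c(45, 65, 90), function(inc) {
    vs <- view_spec(inc, points_per_m2 = 200, noise_sd = 0, seed = 11)
    cl <- sample_point_cloud(tr, terr, vs)
    sum(cl$label == "canopy" & cl$nz < 0) # lower-flank points
  })
  expect_true(counts[1] >= counts[2] && counts[2] >= counts[3])
  expect_equal(counts[[3]], 0)
  # determinism under a fixed seed
  vs <- view_spec(65, seed = 3)
  a <- sample_point_cloud(tr, terr, vs)
  b <- sample_point_cloud(tr, terr, vs)
  expect_identical(a$x, b$x); expect_identical(a$z, b$z)
  # empty truth: empty cloud with warning
  expect_warning(e <- sample_point_cloud(tr[0, ], terr, vs), "empty")
  expect_equal(nrow(e), 0)
})

test_that("DSM rasterization takes per-cell maxima and fills gaps", {
  cl <- data.frame(x = c(0.5, 0.6, 3.5), y = c(0.5, 0.4, 3.5),
                   z = c(2, 3, 7))
  g <- rasterize_dsm(cl, 1, c(0, 0, 4, 4))
  ij <- cell_index(g, 0.5, 0.5)
  expect_equal(g$values[ij$row, ij$col], 3) # max of 2 and 3 in one cell
  ij2 <- cell_index(g, 3.5, 3.5)
  expect_equal(g$values[ij2$row, ij2$col], 7)
  # every empty cell filled from the nearest occupied cell
  expect_true(all(g$values %in% c(2, 3, 7)))
  flat <- data.frame(x = runif(100, 0, 4), y = runif(100, 0, 4), z = 700)
  gf <- rasterize_dsm(flat, 0.5, c(0, 0, 4, 4))
  expect_true(all(gf$values == 700))
  expect_warning(rasterize_dsm(cl, 1, c(100, 100, 104, 104)), "no point")
})

test_that("fixture sets round-trip through the plain-text formats", {
  sim <- cached("mini_sim", {
    cfg <- default_config(seed = 2)$simulate
    cfg$n_trees <- 4; cfg$n_rows <- 2; cfg$points_per_m2 <- 30
    cfg$cell_size <- 0.1; cfg$extent_margin <- 2
    cfg$lidar$enabled <- FALSE
    simulate_orchard_products(cfg, seed = 2)
  })
  outdir <- withr::local_tempdir()
  man <- write_fixture_set(outdir, sim$truth, sim$dsm[["integrated"]],
                           sim$terrain, sim$clouds)
  expect_setequal(names(man$clouds), c("45", "65", "90", "integrated"))
  truth2 <- read.csv(file.path(outdir, man$truth))
  expect_equal(truth2$total_height, sim$truth$total_height)
  cl2 <- read_xyz_csv(file.path(outdir, man$clouds[["45"]]))
  expect_equal(cl2$z, sim$clouds[["45"]]$z, tolerance = 1e-9)
  dsm2 <- read_ascii_grid(file.path(outdir, man$dsm))
  expect_equal(dsm2$values, sim$dsm[["integrated"]]$values, tolerance = 1e-6)
})
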