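test_that("Pearson with stars matches brute-force computation and cor.test", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  res <- pearson_with_stars(x, y, "demo")
  expect_equal(res$r, brute_pearson(x, y), tolerance = 1e-12)
  expect_equal(res$r, 0.82199494, tolerance = 1e-7)
  ct <- cor.test(x, y)
  expect_equal(res$p_value, unname(ct$p.value), tolerance = 1e-12)
  expect_equal(res$r_squared, res$r^2, tolerance = 1e-12)
  # perfect lines
  lin <- pearson_with_stars(x, 2 * x + 1)
  expect_equal(lin$r, 1.0)
  expect_equal(lin$slope, 2.0)
  expect_equal(lin$intercept, 1.0)
  expect_equal(pearson_with_stars(x, -x)$r, -1.0)
  expect_error(pearson_with_stars(x, rep(1, 5)), "variance")
  expect_error(pearson_with_stars(x[1:2], y[1:2]), "at least 3")
})

test_that("slope and intercept equal the least-squares fit", {
  withr::with_seed(21, {
    x <- rnorm(30); y <- 1.7 * x + rnorm(30, sd = 0.3)
  })
  res <- pearson_with_stars(x, y)
  fit <- coef(lm(y ~ x))
  expect_equal(res$intercept, unname(fit[1]), tolerance = 1e-12)
  expect_equal(res$slope, unname(fit[2]), tolerance = 1e-12)
})

test_that("stars follow the conventional thresholds with boundaries in the
           less significant class", {
  expect_equal(orchardtraits:::star_code(c(0.0005, 0.005, 0.04, 0.2)),
               c("***", "**", "*", ""))
  expect_equal(orchardtraits:::star_code(c(0.001, 0.01, 0.05)),
               c("**", "*", ""))
})

test_that("correlation matrix is symmetric with unit diagonal and includes
           estimate-vs-estimate entries", {
  withr::with_seed(5, {
    ref <- setNames(runif(12, 2, 3), 1:12)
    ds <- list(a = ref + rnorm(12, sd = 0.05),
               b = ref + rnorm(12, sd = 0.2))
  })
  for (nm in names(ds)) names(ds[[nm]]) <- names(ref)
  cm <- correlation_matrix(ds, ref)
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(colnames(cm$r), c("ground", "a", "b"))
  expect_equal(cm$r, t(cm$r))
  expect_true("ground vs a" %in% cm$pairs$pair)
  expect_true(any(grepl("a vs b", cm$pairs$pair))) # dataset-vs-dataset
  bad <- ds; names(bad$a) <- 13:24
  expect_error(correlation_matrix(bad, ref), "aligned")
})

test_that("distribution summaries use inclusive interpolation", {
  s <- summarize_distribution(c(2.13, 2.70, 3.05), "heights")
  expect_equal(s$median, 2.70)
  expect_equal(s$min, 2.13); expect_equal(s$max, 3.05)
  cst <- summarize_distribution(rep(4, 7))
  expect_true(all(c(cst$min, cst$q1, cst$median, cst$q3, cst$max) == 4))
  withr::with_seed(6, {
    v <- rnorm(100)
    s2 <- summarize_distribution(v)
    expect_true(s2$min <= s2$q1 && s2$q1 <= s2$median &&
                  s2$median <= s2$q3 && s2$q3 <= s2$max)
  })
  expect_error(summarize_distribution(numeric(0)), "empty")
})

test_that("outlier exclusion joins on tree id and records n", {
  traits <- data.frame(tree_id = 1:20, height_m = runif(20, 2, 3))
  ref <- data.frame(tree_id = 1:20, height_m = runif(20, 2, 3))
  j <- exclude_outliers(traits, ref, excluded_ids = 13)
  expect_equal(attr(j, "n"), 19L)
  expect_false(13 %in% j$tree_id)
  expect_equal(attr(exclude_outliers(traits, ref), "n"), 20L)
  # a reference restricted to 17 trees joins to 17 pairs
  j17 <- exclude_outliers(traits, ref[1:17, ])
  expect_equal(attr(j17, "n"), 17L)
  expect_warning(exclude_outliers(traits, ref, excluded_ids = 99),
                 "not present")
})

test_that("reports are written deterministically with slopes for every pair", {
  cors <- rbind(pearson_with_stars(1:10, (1:10) * 1.1, "m1 vs ground"),
                pearson_with_stars(1:10, c(2:10, 12), "m2 vs ground"))
  sums <- rbind(summarize_distribution(1:10, "ground"),
                summarize_distribution((1:10) * 1.1, "m1"))
  paired <- data.frame(pair = rep(c("m1", "m2"), each = 10),
                       reference = rep(1:10, 2),
                       estimate = c((1:10) * 1.1, c(2:10, 12)))
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  f1 <- build_report(cors, sums, paired, out1)
  f2 <- build_report(cors, sums, paired, out2)
  expect_true(all(c("correlations.csv", "summaries.csv") %in% basename(f1)))
  expect_true("slope" %in% names(read.csv(file.path(out1, "correlations.csv"))))
  expect_identical(readLines(file.path(out1, "correlations.csv")),
                   readLines(file.path(out2, "correlations.csv")))
  expect_identical(readLines(file.path(out1, "summaries.csv")),
                   readLines(file.path(out2, "summaries.csv")))
})
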