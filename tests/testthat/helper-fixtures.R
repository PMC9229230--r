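# Shared fixture builders. Expensive simulations are cached for the session
# so several test files can reuse the same synthetic orchard.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# default-condition orchard, zero coordinate noise, 3 degree bias
noiseless_sim <- function() {
  cached("noiseless_sim", {
    cfg <- default_config(seed = 1)$simulate
    cfg$noise_sd <- 0
    simulate_orchard_products(cfg, seed = 1)
  })
}

# default-condition orchard with the default 0.02 m noise
default_sim <- function() {
  cached("default_sim", {
    simulate_orchard_products(default_config(seed = 1)$simulate, seed = 1)
  })
}

# flat terrain over a small extent
flat_terrain <- function(extent = c(0, 0, 20, 12), cell = 0.1, z = 700) {
  generate_terrain(extent, cell, mean_elevation = z, slope = 0,
                   roughness_sd = 0, seed = 1)
}

# points uniform on an ellipsoid surface
ellipsoid_surface <- function(n, a = 1, b = 0.8, cc = 0.6, seed = 1) {
  withr::with_seed(seed, {
    u <- matrix(stats::rnorm(3 * n), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    data.frame(x = a * u[, 1], y = b * u[, 2], z = cc * u[, 3])
  })
}

# points uniform inside an ellipsoid (rejection sampling)
ellipsoid_solid <- function(n, a = 1, b = 0.8, cc = 0.6, seed = 1) {
  withr::with_seed(seed, {
    P <- matrix(stats::runif(ceiling(3 * n / 0.5) * 3, -1, 1), ncol = 3)
    keep <- P[, 1]^2 + P[, 2]^2 + P[, 3]^2 <= 1
    P <- P[keep, ][seq_len(n), ]
    data.frame(x = a * P[, 1], y = b * P[, 2], z = cc * P[, 3])
  })
}

# brute-force Pearson r from first principles (independent of stats::cor)
brute_pearson <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}
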