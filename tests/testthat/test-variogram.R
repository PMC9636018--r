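test_that("a constant map has zero semivariance everywhere", {
  mesh <- ico(2)
  map <- scalar_map(rep(3, 162), mesh)
  vg <- empirical_variogram(map)
  expect_true(all(vg$gamma[vg$count > 0] == 0))
  expect_true(all(is.na(vg$gamma[vg$count == 0])))
})

test_that("two locations at distance d give semivariance one half", {
  # 0 and 1 at voxel distance 3 mm: gamma = 0.5 * (0 - 1)^2 = 0.5 in the
  # single populated bin.
  grid <- volume_grid(c(2, 1, 1), diag(c(3, 1, 1, 1)))
  map <- scalar_map(c(0, 1), grid)
  vg <- empirical_variogram(map, n_bins = 2, max_quantile = 1)
  populated <- which(vg$count > 0)
  expect_length(populated, 1)
  expect_equal(vg$gamma[populated], 0.5)
  expect_equal(sum(vg$count), 1)
})

test_that("the variogram matches a brute-force all-pairs oracle", {
  mesh <- ico(2) # exhaustive O(L^2) oracle stays cheap
  set.seed(14)
  mask <- rep(TRUE, 162); mask[sample(162, 20)] <- FALSE
  values <- rnorm(162); values[!mask] <- NA
  map <- scalar_map(values, mesh, mask = mask)
  vg <- empirical_variogram(map, n_bins = 10, max_quantile = 0.3)
  orc <- oracle_variogram(values, mask, mesh$vertices, 10, 0.3)
  expect_identical(vg$count, orc$count)
  expect_equal(vg$gamma, orc$gamma, tolerance = 1e-12)
})

test_that("degenerate variogram inputs are rejected", {
  mesh <- ico(1)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 1))
  expect_error(empirical_variogram(map, n_bins = 1),
               class = "spinmaps_invalid_argument")
  empty <- scalar_map(c(1, rep(NA, 41)), mesh)
  expect_error(empirical_variogram(empty),
               class = "spinmaps_insufficient_data")
})

test_that("forcing alpha = 0, beta = 1 yields the smoothed permutation", {
  mesh <- ico(2)
  map <- sample_grf(mesh, grf_spec(0.3, seed = 6))
  scale <- 0.2
  ens <- variogram_null(map, n_null = 2, seed = 9, kernel_scales = scale,
                        force_fit = list(alpha = 0, beta = 1, scale = scale),
                        rescale = FALSE)
  seeds <- spinmaps:::derive_seeds(9, 2)
  kern <- spinmaps:::smoothing_kernel(spinmaps:::point_space(mesh$vertices), scale)
  for (k in 1:2) {
    draws <- spinmaps:::with_seed(seeds[k], {
      list(perm = sample.int(162), z = rnorm(162))
    })
    expected <- as.numeric(kern %*% map$values[draws$perm])
    expect_equal(ens$surrogates[k, ], expected, tolerance = 1e-12)
  }
})

test_that("variogram surrogates preserve the source mean and variance", {
  mesh <- ico(2)
  mask <- sample_medial_wall(mesh, 0.1, seed = 3)
  map <- sample_grf(mesh, grf_spec(0.3, seed = 2), mask = mask)
  ens <- variogram_null(map, n_null = 10, seed = 4)
  x <- map$values[mask]
  for (k in 1:10) {
    y <- ens$surrogates[k, mask]
    expect_lt(abs(mean(y) - mean(x)), 1e-9)
    expect_lt(abs(var(y) - var(x)), 1e-9)
    expect_true(all(is.na(ens$surrogates[k, !mask])))
  }
})

test_that("variogram ensembles are deterministic and record their fits", {
  mesh <- ico(2)
  map <- sample_grf(mesh, grf_spec(0.3, seed = 2))
  e1 <- variogram_null(map, n_null = 4, seed = 8)
  e2 <- variogram_null(map, n_null = 4, seed = 8)
  expect_identical(e1$surrogates, e2$surrogates)
  fits <- e1$params$fits
  expect_equal(nrow(fits), 4)
  expect_true(all(fits$sse >= 0))
  expect_true(all(fits$kernel_scale %in% e1$params$kernel_scales))
})

test_that("a zero-variance input is reported as a numerical failure", {
  mesh <- ico(1)
  map <- scalar_map(rep(1, 42), mesh)
  expect_error(variogram_null(map, n_null = 1, seed = 1),
               class = "spinmaps_numerical_error")
})
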