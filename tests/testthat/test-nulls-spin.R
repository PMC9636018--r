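test_that("an identity rotation returns the map unchanged", {
  mesh <- ico(2)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 5))
  ens <- spin_vertex(map, mesh, n_null = 1, seed = 1,
                     rotations = list(identity_rotation()))
  expect_identical(ens$surrogates[1, ], map$values)
})

test_that("spinning a constant map changes nothing", {
  mesh <- ico(1)
  map <- scalar_map(rep(2.5, 42), mesh)
  ens <- spin_vertex(map, mesh, n_null = 5, seed = 3)
  expect_true(all(ens$surrogates == 2.5))
})

test_that("vertex spins match the exhaustive rotated-nearest oracle", {
  mesh <- ico(2)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 8))
  seeds <- spinmaps:::derive_seeds(42, 5)
  ens <- spin_vertex(map, mesh, n_null = 5, seed = 42)
  for (k in 1:5) {
    expected <- oracle_spin(map$values, mesh$vertices, sample_rotation(seeds[k])$R)
    expect_identical(ens$surrogates[k, ], expected)
  }
})

test_that("spin surrogates only rearrange the source values", {
  mesh <- ico(2)
  mask <- sample_medial_wall(mesh, 0.15, seed = 2)
  map <- sample_grf(mesh, grf_spec(0.3, seed = 4), mask = mask)
  ens <- spin_vertex(map, mesh, n_null = 20, seed = 6)
  src_valid <- map$values[map$mask]
  for (k in c(1, 10, 20)) {
    got <- ens$surrogates[k, ]
    expect_true(all(got[!is.na(got)] %in% src_valid))
  }
  # Vertices assigned from the medial wall are NA, never invented.
  expect_true(anyNA(ens$surrogates))
})

test_that("two-hemisphere spins mirror the rotation on the second mesh", {
  mesh_l <- ico(1, "left"); mesh_r <- ico(1, "right")
  map_l <- sample_grf(mesh_l, grf_spec(0.2, seed = 1))
  map_r <- sample_grf(mesh_r, grf_spec(0.2, seed = 2))
  ens <- spin_vertex(map_l, mesh_l, n_null = 3, seed = 11,
                     mesh_other = mesh_r, map_other = map_r)
  expect_equal(dim(ens$surrogates), c(3L, 84L))
  seeds <- spinmaps:::derive_seeds(11, 3)
  r1 <- sample_rotation(seeds[1])
  expect_identical(ens$surrogates[1, 1:42],
                   oracle_spin(map_l$values, mesh_l$vertices, r1$R))
  expect_identical(ens$surrogates[1, 43:84],
                   oracle_spin(map_r$values, mesh_r$vertices, r1$R_mirror))
})

test_that("precomputed spin indices reproduce seeded generation", {
  mesh <- ico(2)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 9))
  idx <- spin_indices(mesh, 4, seed = 13)
  a <- spin_vertex(map, mesh, n_null = 4, seed = 13)
  b <- spin_vertex(map, mesh, n_null = 4, seed = 13, indices = idx)
  expect_identical(a$surrogates, b$surrogates)
})

test_that("spin ensembles are deterministic and cacheable", {
  mesh <- ico(1)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 1))
  e1 <- spin_vertex(map, mesh, n_null = 8, seed = 21)
  e2 <- spin_vertex(map, mesh, n_null = 8, seed = 21)
  expect_identical(e1$surrogates, e2$surrogates)
  expect_identical(e1$cache_key, e2$cache_key)
  cache_dir <- withr::local_tempdir()
  cache_ensemble(e1, cache_dir)
  hit <- fetch_ensemble(e1$cache_key, cache_dir)
  expect_identical(hit$surrogates, e1$surrogates)
  expect_null(fetch_ensemble("no_such_key", cache_dir))
})

test_that("a fully masked map is rejected", {
  mesh <- ico(0)
  map <- scalar_map(rep(NA_real_, 12), mesh, mask = rep(FALSE, 12))
  expect_error(spin_vertex(map, mesh, n_null = 2, seed = 1),
               class = "spinmaps_invalid_argument")
})

test_that("parcellated spins with an identity rotation recover the input", {
  mesh <- ico(2)
  parc <- sample_parcellation(mesh, 12, seed = 3)
  values <- rnorm(12)
  for (strategy in c("discard", "ignore", "nearest")) {
    ens <- spin_parcellated(values, parc, strategy, n_null = 1, seed = 1,
                            rotations = list(identity_rotation()))
    expect_equal(ens$surrogates[1, ], values, tolerance = 1e-12)
  }
})

test_that("parcellated spins match the project-rotate-aggregate oracle", {
  mesh <- ico(3)
  parc <- sample_parcellation(mesh, 20, seed = 5)
  mask <- sample_medial_wall(mesh, 0.2, seed = 7)
  set.seed(31)
  values <- rnorm(20)
  seeds <- spinmaps:::derive_seeds(77, 3)
  for (strategy in c("discard", "ignore", "nearest")) {
    ens <- spin_parcellated(values, parc, strategy, n_null = 3, seed = 77,
                            mask = mask)
    for (k in 1:3) {
      expected <- oracle_spin_parcellated(
        values, parc$labels, mesh$vertices, mask,
        sample_rotation(seeds[k])$R, strategy, 1:20)
      expect_equal(ens$surrogates[k, ], expected, tolerance = 1e-12)
    }
  }
})

test_that("the discard strategy leaves wall-covered parcels missing", {
  mesh <- ico(2)
  parc <- sample_parcellation(mesh, 8, seed = 1)
  # Mask out every vertex: any rotation must yield all-NA parcel values
  # except where the mask leaves data. Here: mask out one parcel's worth.
  mask <- parc$labels != 3L
  ens <- spin_parcellated(rnorm(8), parc, "discard", n_null = 1, seed = 1,
                          rotations = list(identity_rotation()), mask = mask)
  expect_true(is.na(ens$surrogates[1, 3]))
  expect_true(all(!is.na(ens$surrogates[1, -3])))
  # The nearest strategy fills that parcel from its closest neighbour.
  ens2 <- spin_parcellated(rnorm(8), parc, "nearest", n_null = 1, seed = 1,
                           rotations = list(identity_rotation()), mask = mask)
  expect_true(all(!is.na(ens2$surrogates)))
})
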