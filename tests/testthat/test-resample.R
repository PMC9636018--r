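test_that("applying an identity correspondence returns the input", {
  mesh <- ico(2)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 1))
  tab <- nearest_source(mesh, mesh)
  out <- apply_correspondence(map, tab, mesh)
  expect_identical(out$values, map$values)
})

test_that("nearest-neighbour downsampling matches a per-vertex scan", {
  src <- ico(4); tgt <- ico(2)
  map <- sample_grf(src, grf_spec(0.3, seed = 2))
  out <- apply_correspondence(map, nearest_source(src, tgt), tgt)
  orc <- oracle_nearest(src$vertices, tgt$vertices)
  expect_identical(out$values, map$values[orc$index])
  # Constant maps stay constant, masked sources propagate missingness.
  const <- scalar_map(rep(7, 2562), src)
  expect_true(all(apply_correspondence(const, nearest_source(src, tgt), tgt)$values == 7))
  masked <- scalar_map(replace(map$values, 1:162, NA), src)
  down <- apply_correspondence(masked, nearest_source(src, tgt), tgt)
  expect_true(all(is.na(down$values))) # shared prefix vertices map to themselves
})

test_that("k = 1 interpolation reduces to the nearest-source lookup", {
  src <- ico(2); tgt <- ico(1)
  map <- sample_grf(src, grf_spec(0.2, seed = 3))
  a <- knn_interpolate(map, src, tgt, k = 1)
  b <- apply_correspondence(map, nearest_source(src, tgt), tgt)
  expect_equal(a$values, b$values, tolerance = 1e-15)
  const <- scalar_map(rep(-2, 162), src)
  expect_true(all(knn_interpolate(const, src, tgt, k = 5)$values == -2))
  expect_error(knn_interpolate(map, src, tgt, k = 0),
               class = "spinmaps_invalid_argument")
})

test_that("k-NN interpolation averages the k nearest valid sources", {
  # Irregular jittered mesh so nearest-neighbour sets are unambiguous.
  set.seed(60)
  pts <- matrix(rnorm(36), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2))
  src <- spherical_mesh(pts, ico(0)$faces, "left", "jittered")
  tgt <- ico(0)
  values <- rnorm(12)
  mask <- rep(TRUE, 12); mask[c(2, 9)] <- FALSE
  map <- scalar_map(replace(values, !mask, NA), src)
  out <- knn_interpolate(map, src, tgt, k = 3)
  valid <- which(mask)
  for (j in 1:12) {
    d <- sqrt(rowSums(sweep(pts[valid, ], 2, tgt$vertices[j, ])^2))
    expected <- mean(values[valid][order(d)[1:3]])
    expect_equal(out$values[j], expected, tolerance = 1e-12)
  }
  # Fewer valid sources than k: use what exists.
  sparse <- scalar_map(replace(values, -c(1, 5), NA), src)
  out2 <- knn_interpolate(sparse, src, tgt, k = 5)
  expect_true(all(out2$values %in% c(mean(values[c(1, 5)]))))
})

test_that("align_pair lands on the lower-resolution space", {
  a <- sample_grf(ico(4), grf_spec(0.3, seed = 1))
  b <- sample_grf(ico(2), grf_spec(0.3, seed = 2))
  al <- align_pair(a, b)
  expect_length(al[[1]]$values, 162)
  expect_length(al[[2]]$values, 162)
  expect_identical(al[[2]]$values, b$values) # low-res map untouched
  # Equal spaces pass through unchanged.
  same <- align_pair(b, sample_grf(ico(2), grf_spec(0.3, seed = 3)))
  expect_identical(same[[1]]$values, b$values)
  # Explicit override upsamples instead.
  up <- align_pair(a, b, target = ico(4))
  expect_length(up[[2]]$values, 2562)
  expect_identical(up[[1]]$values, a$values)
})

test_that("surface-to-volume alignment of continuous data is refused", {
  surf <- sample_grf(ico(1), grf_spec(0.2, seed = 1))
  vol <- scalar_map(rnorm(27), volume_grid(c(3, 3, 3)))
  expect_error(align_pair(surf, vol), class = "spinmaps_unsupported_transform")
  # Same-grid volumes pass through.
  vol2 <- scalar_map(rnorm(27), volume_grid(c(3, 3, 3)))
  expect_identical(align_pair(vol, vol2)[[1]]$values, vol$values)
})

test_that("downsampling inverts upsampling on nested icospheres", {
  lo <- ico(2); hi <- ico(4)
  map <- sample_grf(lo, grf_spec(0.3, seed = 5))
  up <- apply_correspondence(map, nearest_source(lo, hi), hi)
  down <- apply_correspondence(up, nearest_source(hi, lo), lo)
  expect_identical(down$values, map$values)
})

test_that("parcel means match a brute-force group-by", {
  mesh <- ico(3)
  parc <- sample_parcellation(mesh, 20, seed = 4)
  mask <- sample_medial_wall(mesh, 0.15, seed = 6)
  map <- sample_grf(mesh, grf_spec(0.3, seed = 7), mask = mask)
  got <- parcellate_map(map, parc)
  for (id in 1:20) {
    v <- map$values[parc$labels == id & mask]
    expected <- if (length(v)) mean(v) else NA_real_
    expect_equal(unname(got[id]), expected, tolerance = 1e-12)
  }
  # Piecewise-constant maps are recovered exactly.
  pc <- scalar_map((1:20)[parc$labels], mesh)
  expect_identical(unname(parcellate_map(pc, parc)), as.numeric(1:20))
})

test_that("parcellation relabeling permutes parcel means with the ids", {
  mesh_l <- ico(2, "left"); mesh_r <- ico(2, "right")
  parc_l <- sample_parcellation(mesh_l, 6, seed = 1)
  parc_r <- sample_parcellation(mesh_r, 4, seed = 2)
  re <- relabel_consecutive(parc_l, parc_r)
  map_l <- sample_grf(mesh_l, grf_spec(0.3, seed = 3))
  means_orig <- parcellate_map(map_l, parc_l)
  means_re <- parcellate_map(map_l, re$left)
  rows <- re$id_map[re$id_map$hemisphere == "left", ]
  expect_identical(unname(means_re[as.character(rows$id)]),
                   unname(means_orig[as.character(rows$original_id)]))
})
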