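test_that("the masked Pearson correlation matches hand computations", {
  mesh <- ico(0)
  x <- scalar_map(c(1, 2, 3, 4, rep(0, 8)), mesh)
  expect_equal(pearson_masked(x, x), 1)
  neg <- scalar_map(-x$values, mesh)
  expect_equal(pearson_masked(x, neg), -1)
  # Complete pairs (1,2,4) vs (1,2,5): r computed from the definition.
  a <- c(1, 2, 3, 4); b <- c(1, 2, NA, 5)
  am <- scalar_map(c(a, rep(NA, 8)), mesh)
  bm <- scalar_map(c(b, rep(NA, 8)), mesh)
  ac <- c(1, 2, 4); bc <- c(1, 2, 5)
  expected <- sum((ac - mean(ac)) * (bc - mean(bc))) /
    sqrt(sum((ac - mean(ac))^2) * sum((bc - mean(bc))^2))
  expect_equal(pearson_masked(am, bm), expected, tolerance = 1e-15)
})

test_that("degenerate correlation inputs raise typed errors", {
  mesh <- ico(0)
  few <- scalar_map(c(1, 2, rep(NA, 10)), mesh)
  other <- scalar_map(rnorm(12), mesh)
  expect_error(pearson_masked(few, other), class = "spinmaps_insufficient_data")
  const <- scalar_map(rep(1, 12), mesh)
  expect_error(pearson_masked(const, other), class = "spinmaps_numerical_error")
})

test_that("a degenerate ensemble of copies gives p = 1", {
  mesh <- ico(1)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 1))
  tgt <- sample_grf(mesh, grf_spec(0.2, seed = 2))
  ens <- spin_vertex(map, mesh, n_null = 50, seed = 1,
                     rotations = rep(list(identity_rotation()), 50))
  res <- compare_maps(map, tgt, ens)
  expect_equal(res$p_value, 1)
})

test_that("the add-one estimator gives 1/(n+1) for an extreme statistic", {
  mesh <- ico(2)
  map <- sample_grf(mesh, grf_spec(0.3, seed = 3))
  # Ensemble of i.i.d. shuffles: with 162 vertices no shuffle comes near
  # the observed r = 1 of the map against itself, so the observed
  # statistic strictly beats all 1000 surrogates.
  set.seed(5)
  surr <- t(replicate(1000, sample(map$values)))
  ens <- null_ensemble(surr, "spin_vertex", seed = 5)
  res <- compare_maps(map, map, ens)
  expect_lt(max(abs(res$null_statistics)), 1) # premise of the check
  expect_equal(res$p_value, 1 / 1001, tolerance = 1e-12)
  expect_equal(res$n_complete, 162L)
  expect_identical(res$framework, "spin_vertex")
})

test_that("p-values ignore surrogate ordering and never reach zero", {
  mesh <- ico(1)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 4))
  tgt <- sample_grf(mesh, grf_spec(0.2, seed = 5))
  ens <- spin_vertex(map, mesh, n_null = 99, seed = 6)
  res <- compare_maps(map, tgt, ens)
  shuffled <- ens
  set.seed(1)
  shuffled$surrogates <- ens$surrogates[sample(99), ]
  expect_equal(compare_maps(map, tgt, shuffled)$p_value, res$p_value)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("custom metrics are honoured and validated", {
  mesh <- ico(1)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 7))
  tgt <- sample_grf(mesh, grf_spec(0.2, seed = 8))
  ens <- spin_vertex(map, mesh, n_null = 20, seed = 9)
  res <- compare_maps(map, tgt, ens, metric = function(x, y) mean(abs(x - y)))
  expect_identical(res$metric_name, "custom")
  expect_equal(res$statistic, mean(abs(map$values - tgt$values)))
  expect_error(compare_maps(map, tgt, ens, metric = function(x, y) NaN),
               class = "spinmaps_numerical_error")
})

test_that("swapping the roles under symmetric nulls preserves the p-value", {
  mesh <- ico(1)
  map <- sample_grf(mesh, grf_spec(0.2, seed = 10))
  tgt <- sample_grf(mesh, grf_spec(0.2, seed = 11))
  ens <- spin_vertex(map, mesh, n_null = 50, seed = 12)
  p_fwd <- compare_maps(map, tgt, ens, null_on = "source")$p_value
  p_rev <- compare_maps(tgt, map, ens, null_on = "target")$p_value
  expect_equal(p_fwd, p_rev)
})

test_that("BH adjustment matches the step-up oracle", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.20)
  out <- fdr_bh(p, alpha = 0.05)
  # Step-up oracle: largest k with p_(k) <= k/m * alpha rejected; adjusted
  # values by the cumulative minimum from the largest rank down.
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  expected_adj <- numeric(m); expected_adj[ord] <- pmin(adj, 1)
  expect_equal(out$adjusted, expected_adj, tolerance = 1e-15)
  thresholds <- p[ord] <= seq_len(m) / m * 0.05
  k_max <- if (any(thresholds)) max(which(thresholds)) else 0
  expected_rej <- logical(m)
  if (k_max > 0) expected_rej[ord[seq_len(k_max)]] <- TRUE
  expect_identical(out$rejected, expected_rej)

  expect_true(all(fdr_bh(rep(0.01, 8))$rejected))
  expect_length(fdr_bh(numeric(0))$adjusted, 0)
  expect_error(fdr_bh(c(0.5, 1.2)), class = "spinmaps_invalid_argument")
})

test_that("batch comparison produces one corrected row per target", {
  mesh <- ico(2)
  src <- sample_grf(mesh, grf_spec(0.3, seed = 20))
  targets <- lapply(1:13, function(s) sample_grf(mesh, grf_spec(0.3, seed = 20 + s)))
  tab <- compare_many(src, targets, n_null = 50, seed = 33)
  expect_equal(nrow(tab), 13)
  expect_true(all(tab$status == "ok"))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(all(tab$p_adjusted >= tab$p_value))
  expect_identical(tab$framework, rep("spin_vertex", 13))
  # Deterministic rerun.
  tab2 <- compare_many(src, targets, n_null = 50, seed = 33)
  expect_identical(tab$statistic, tab2$statistic)
  expect_identical(tab$p_value, tab2$p_value)
  prov <- attr(tab, "provenance")
  expect_identical(prov$correction, "benjamini-hochberg")
  expect_identical(prov$alignment, "lower-resolution rule")
})

test_that("per-target failures are flagged rather than fatal", {
  mesh <- ico(1)
  src <- sample_grf(mesh, grf_spec(0.2, seed = 1))
  bad <- scalar_map(rep(1, 42), mesh) # zero variance
  good <- sample_grf(mesh, grf_spec(0.2, seed = 2))
  tab <- compare_many(src, list(bad, good), n_null = 20, seed = 3)
  expect_match(tab$status[1], "error")
  expect_identical(tab$status[2], "ok")
  expect_true(is.na(tab$statistic[1]))
})

test_that("mixed-resolution targets are aligned before comparison", {
  src <- sample_grf(ico(3), grf_spec(0.3, seed = 40))
  targets <- list(sample_grf(ico(2), grf_spec(0.3, seed = 41)),
                  sample_grf(ico(3), grf_spec(0.3, seed = 42)))
  tab <- compare_many(src, targets, n_null = 30, seed = 44)
  expect_true(all(tab$status == "ok"))
  expect_identical(tab$n_complete, c(162L, 642L))
})
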