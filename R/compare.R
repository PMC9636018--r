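# The statistical comparison workflow: similarity statistic on
# pairwise-complete locations, two-sided surrogate p-values with the
# add-one estimator, batch comparison of one source map against many
# targets, and Benjamini-Hochberg correction across targets.

#' Pearson correlation over pairwise-complete locations
#'
#' @param x,y [scalar_map()]s on spaces of equal size (or plain numeric
#'   vectors).
#' @return Pearson's r over locations valid in both maps.
#' @export
pearson_masked <- function(x, y) {
  vx <- if (inherits(x, "scalar_map")) x$values else as.numeric(x)
  vy <- if (inherits(y, "scalar_map")) y$values else as.numeric(y)
  if (length(vx) != length(vy)) stop_invalid("maps live on spaces of different size")
  ok <- !is.na(vx) & !is.na(vy)
  if (sum(ok) < 3L) stop_insufficient("fewer than 3 pairwise-complete locations")
  if (stats::sd(vx[ok]) == 0 || stats::sd(vy[ok]) == 0) {
    stop_numerical("undefined statistic: zero variance over complete locations")
  }
  stats::cor(vx[ok], vy[ok])
}

#' Compare two maps against a null ensemble
#'
#' Computes the similarity statistic (Pearson's r by default, or any pure
#' function of two equal-length numeric vectors) on the observed pair, then
#' on each surrogate substituted for the nulled map, and returns the
#' two-sided permutation p-value with the add-one estimator
#' `p = (1 + #[|null| >= |obs|]) / (1 + n_null)`. Missingness is handled by
#' pairwise-complete deletion, applied identically to the observed and the
#' surrogate statistics.
#'
#' @param source,target [scalar_map()]s in the same space.
#' @param nulls a [null_ensemble()] generated for one of the two maps.
#' @param metric optional `function(x, y)` returning a scalar; receives the
#'   pairwise-complete value vectors.
#' @param null_on which map the ensemble replaces: `"source"` (default,
#'   matching the workflow of spinning the source map) or `"target"`.
#' @return A `comparison_result`: list with `statistic`,
#'   `null_statistics`, `p_value`, `n_complete`, `metric_name`,
#'   `framework`, `seed`.
#' @export
compare_maps <- function(source, target, nulls, metric = NULL,
                         null_on = c("source", "target")) {
  null_on <- match.arg(null_on)
  if (length(source$values) != length(target$values)) {
    stop_invalid("maps live on spaces of different size")
  }
  if (ncol(nulls$surrogates) != length(source$values)) {
    stop_invalid("null ensemble was generated for a different space (",
                 ncol(nulls$surrogates), " vs ", length(source$values),
                 " locations)")
  }
  metric_name <- if (is.null(metric)) "pearson" else "custom"
  stat_fun <- function(vx, vy) {
    ok <- !is.na(vx) & !is.na(vy)
    if (sum(ok) < 3L) return(NA_real_)
    if (is.null(metric)) {
      if (stats::sd(vx[ok]) == 0 || stats::sd(vy[ok]) == 0) return(NA_real_)
      stats::cor(vx[ok], vy[ok])
    } else {
      metric(vx[ok], vy[ok])
    }
  }
  observed <- stat_fun(source$values, target$values)
  if (!is.finite(observed)) {
    stop_numerical("similarity metric is not finite on the observed maps")
  }
  fixed <- if (null_on == "source") target$values else source$values
  null_stats <- apply(nulls$surrogates, 1L, function(s) stat_fun(s, fixed))
  n_used <- sum(is.finite(null_stats))
  p <- (1 + sum(abs(null_stats[is.finite(null_stats)]) >= abs(observed))) /
    (1 + n_used)
  structure(
    list(statistic = observed, null_statistics = null_stats, p_value = p,
         n_complete = sum(!is.na(source$values) & !is.na(target$values)),
         metric_name = metric_name, framework = nulls$framework,
         seed = nulls$seed),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("comparison_result: %s = %.4f, p = %.4g (%s, %d surrogates, %d complete locations)\n",
              x$metric_name, x$statistic, x$p_value, x$framework,
              length(x$null_statistics), x$n_complete))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and the rejection
#' set at level `alpha`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level in `(0, 1)`.
#' @return List with `adjusted` (numeric) and `rejected` (logical).
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) {
    return(list(adjusted = numeric(0), rejected = logical(0)))
  }
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    stop_invalid("'alpha' must be in (0, 1)")
  }
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, rejected = !is.na(adjusted) & adjusted <= alpha)
}

# Generate (or fetch from cache) the null ensemble appropriate for a map.
# Framework "auto" resolves to the spin test for surface spaces and to
# variogram matching for volumetric spaces.
make_nulls <- function(map, framework = "auto", n_null = 1000L, seed = 1L,
                       cache_dir = NULL, ...) {
  if (identical(framework, "auto")) {
    framework <- if (inherits(map$space, "volume_grid")) "variogram" else "spin_vertex"
  }
  params <- switch(framework,
    spin_vertex = list(n_null = n_null, two_hemisphere = FALSE),
    variogram = NULL, # key computed after generation (depends on settings)
    moran = list(n_null = n_null, eig_tol = 1e-8),
    stop_invalid("unknown null framework: ", framework)
  )
  key <- if (!is.null(params) && !is.null(cache_dir)) {
    content_digest(list(space_digest(map$space), framework, n_null, seed, params))
  } else {
    NULL
  }
  if (!is.null(key)) {
    hit <- fetch_ensemble(key, cache_dir)
    if (!is.null(hit)) return(hit)
  }
  ens <- switch(framework,
    spin_vertex = spin_vertex(map, map$space, n_null = n_null, seed = seed),
    variogram = variogram_null(map, n_null = n_null, seed = seed, ...),
    moran = moran_null(map, build_weights(map$space, "edge_adjacency"),
                       n_null = n_null, seed = seed)
  )
  if (!is.null(cache_dir)) cache_ensemble(ens, cache_dir)
  ens
}

#' Compare one source map against many targets
#'
#' For each target the pair is first brought into a common space by the
#' lower-resolution rule ([align_pair()]), a null ensemble for the aligned
#' source is generated (or fetched from cache) in that space, and
#' [compare_maps()] is run. P-values are corrected across targets with
#' [fdr_bh()]. Per-target failures are caught and flagged in the `status`
#' column rather than aborting the batch.
#'
#' @param source a [scalar_map()].
#' @param targets list of [scalar_map()]s.
#' @param framework `"auto"` (spin for surface comparison spaces, variogram
#'   for volumetric), or an explicit framework name.
#' @param n_null surrogates per comparison (default 1000).
#' @param seed integer seed.
#' @param alpha FDR level.
#' @param metric optional custom similarity `function(x, y)`.
#' @param cache_dir optional ensemble cache directory; comparisons sharing
#'   a space reuse the same ensemble.
#' @return A data.frame (class `comparison_table`) with one row per target:
#'   `target`, `statistic`, `p_value`, `p_adjusted`, `rejected`,
#'   `n_complete`, `framework`, `status`. Provenance (seed, n_null, alpha,
#'   frameworks) is attached as the `"provenance"` attribute.
#' @export
compare_many <- function(source, targets, framework = "auto", n_null = 1000L,
                         seed = 1L, alpha = 0.05, metric = NULL,
                         cache_dir = NULL) {
  if (length(targets) == 0L) stop_invalid("no target maps supplied")
  seed <- assert_seed(seed)
  n <- length(targets)
  rows <- vector("list", n)
  # One ensemble per distinct comparison space: cache within the call too.
  local_cache <- new.env(parent = emptyenv())
  for (t in seq_len(n)) {
    tgt <- targets[[t]]
    tgt_name <- if (nzchar(tgt$name)) tgt$name else paste0("target_", t)
    rows[[t]] <- tryCatch({
      aligned <- align_pair(source, tgt)
      src_a <- aligned[[1L]]; tgt_a <- aligned[[2L]]
      skey <- paste0(space_digest(src_a$space), "_",
                     content_digest(src_a$values))
      nulls <- local_cache[[skey]]
      if (is.null(nulls)) {
        nulls <- make_nulls(src_a, framework = framework, n_null = n_null,
                            seed = seed, cache_dir = cache_dir)
        local_cache[[skey]] <- nulls
      }
      res <- compare_maps(src_a, tgt_a, nulls, metric = metric)
      data.frame(target = tgt_name, statistic = res$statistic,
                 p_value = res$p_value, n_complete = res$n_complete,
                 framework = res$framework, status = "ok",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(target = tgt_name, statistic = NA_real_, p_value = NA_real_,
                 n_complete = NA_integer_, framework = NA_character_,
                 status = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  corr <- fdr_bh(out$p_value, alpha)
  out$p_adjusted <- corr$adjusted
  out$rejected <- corr$rejected
  out <- out[, c("target", "statistic", "p_value", "p_adjusted", "rejected",
                 "n_complete", "framework", "status")]
  attr(out, "provenance") <- list(
    seed = seed, n_null = n_null, alpha = alpha,
    framework_request = framework,
    frameworks_used = unique(out$framework[out$status == "ok"]),
    p_value_type = "two-sided permutation, add-one estimator",
    correction = "benjamini-hochberg",
    alignment = "lower-resolution rule",
    version = as.character(utils::packageVersion("spinmaps"))
  )
  class(out) <- c("comparison_table", "data.frame")
  out
}

#' Write a comparison table with its provenance sidecar
#'
#' Tab-separated values plus a JSON sidecar recording frameworks, seed,
#' `n_null` and software version.
#'
#' @param table a `comparison_table` from [compare_many()].
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(attr(table, "provenance"), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
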