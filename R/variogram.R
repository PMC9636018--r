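# Variogram-matching generative nulls. Values are randomly permuted (which
# destroys spatial autocorrelation), then smoothed and rescaled so that the
# variogram of the surrogate matches the variogram of the original map:
#   y = |beta|^(1/2) x' + |alpha|^(1/2) z,   z ~ N(0, 1)
# with alpha, beta fit by least squares between the variogram of the
# original data and that of the smoothed permuted data. This framework
# needs only a distance structure, so it works identically for surface
# and volumetric spaces; it is the default null for volumetric data,
# where no sphere exists to spin.

#' Empirical variograms
#'
#' Semivariance `gamma(bin) = 0.5 * mean[(x_i - x_j)^2]` over location
#' pairs whose chord (surface) or world-mm (volume) distance falls in the
#' bin. Bins are evenly spaced from 0 to the `max_quantile` quantile of
#' pairwise distances; pairs involving a masked location are excluded, and
#' empty bins carry `NA` semivariance.
#'
#' @param map a [scalar_map()].
#' @param n_bins number of distance bins (>= 2).
#' @param max_quantile upper quantile of pairwise distances to bin up to.
#' @param max_pairs cap on the number of pairs; when the space has more
#'   than `10^4` locations, pairs are subsampled (seeded) to this count.
#' @param seed seed for the pair subsample (only used when subsampling).
#' @return An object of class `variogram`: a data.frame with columns
#'   `bin_center`, `gamma`, `count`.
#' @export
empirical_variogram <- function(map, n_bins = 25L, max_quantile = 0.25,
                                max_pairs = 1e5, seed = 1L) {
  if (n_bins < 2L) stop_invalid("'n_bins' must be >= 2")
  if (sum(map$mask) < 2L) stop_insufficient("need >= 2 valid locations")
  ps <- pair_structure(map$space, n_bins = n_bins, max_quantile = max_quantile,
                       max_pairs = max_pairs, seed = seed)
  variogram_from_pairs(map$values, map$mask, ps)
}

# Precomputed pair structure for one space: pair indices (i, j), their
# distances, the bin breaks and each pair's bin. Cached per
# (space, n_bins, max_quantile) since it is the dominant cost.
pair_structure <- function(space, n_bins, max_quantile, max_pairs = 1e5,
                           seed = 1L) {
  key <- paste0("P_", space_digest(space), "_", n_bins, "_",
                format(max_quantile, digits = 17), "_", format(max_pairs), "_", seed)
  ps <- .geom_cache[[key]]
  if (!is.null(ps)) return(ps)
  L <- n_locations(space)
  if (L > 1e4) {
    pick <- with_seed(seed, {
      i <- sample.int(L, max_pairs, replace = TRUE)
      j <- sample.int(L, max_pairs, replace = TRUE)
      keep <- i != j
      cbind(pmin(i, j)[keep], pmax(i, j)[keep])
    })
    pick <- unique(pick)
    i <- pick[, 1L]; j <- pick[, 2L]
    coords <- location_coords(space)
    d <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  } else {
    coords <- location_coords(space)
    idx <- which(upper.tri(matrix(TRUE, L, L)), arr.ind = TRUE)
    i <- idx[, 1L]; j <- idx[, 2L]
    # Direct subtraction (not a precomputed distance matrix) so boundary
    # decisions at the distance cutoff agree bitwise with the definition.
    d <- sqrt(rowSums((coords[i, , drop = FALSE] - coords[j, , drop = FALSE])^2))
  }
  dmax <- stats::quantile(d, max_quantile, names = FALSE)
  keep <- d <= dmax & d > 0
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  breaks <- seq(0, dmax, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(d, breaks, rightmost.closed = TRUE), 1L), n_bins)
  ps <- list(i = i, j = j, d = d, bin = bin, breaks = breaks,
             centers = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
             n_bins = as.integer(n_bins))
  .geom_cache[[key]] <- ps
  ps
}

variogram_from_pairs <- function(values, mask, ps) {
  ok <- mask[ps$i] & mask[ps$j]
  sq <- (values[ps$i[ok]] - values[ps$j[ok]])^2
  bin <- ps$bin[ok]
  count <- tabulate(bin, nbins = ps$n_bins)
  sums <- rep(0, ps$n_bins)
  t <- tapply(sq, bin, sum)
  sums[as.integer(names(t))] <- t
  gamma <- ifelse(count > 0L, 0.5 * sums / count, NA_real_)
  structure(data.frame(bin_center = ps$centers, gamma = gamma, count = count),
            class = c("variogram", "data.frame"))
}

# Least-squares fit of gamma_orig ~ beta * gamma_smoothed + alpha over
# non-empty bins, constrained so that the surrogate's variance matches the
# source (beta * var_sm + alpha = var_orig) with a nonnegative nugget
# (0 <= alpha <= var_orig). The constraint keeps the final
# rescale-to-source-variance step from distorting the matched variogram,
# and the clamp stops a negative fitted intercept from turning into
# positive noise variance through the |alpha|^(1/2) term.
fit_variogram <- function(gamma_orig, gamma_smoothed, var_orig, var_smoothed) {
  ok <- is.finite(gamma_orig) & is.finite(gamma_smoothed)
  if (sum(ok) < 2L) return(NULL)
  a <- gamma_smoothed[ok] - var_smoothed
  b <- gamma_orig[ok] - var_orig
  if (sum(a^2) < 1e-30) return(NULL)
  beta <- sum(a * b) / sum(a^2)
  beta <- min(max(beta, 0), var_orig / var_smoothed)
  alpha <- var_orig - beta * var_smoothed
  list(alpha = alpha, beta = beta, sse = sum((b - beta * a)^2))
}

#' Variogram-matching surrogate maps
#'
#' For each surrogate: permute the valid values; smooth the permutation at
#' each candidate kernel scale; regress the original variogram on the
#' smoothed permutation's variogram (`gamma_orig ~ beta * gamma_sm + alpha`,
#' least squares over non-empty bins, constrained to a nonnegative nugget
#' and to `beta * var_sm + alpha = var_orig` so the matched variogram
#' survives the final rescaling); keep the scale with the smallest
#' residual sum of squares; emit
#' `y = |beta|^(1/2) x'_sm + |alpha|^(1/2) z` with fresh Gaussian noise `z`;
#' rescale `y` to the source mean and variance.
#'
#' @param map a [scalar_map()] on a surface or volumetric space.
#' @param n_null number of surrogates.
#' @param seed integer seed.
#' @param n_bins,max_quantile variogram settings (see
#'   [empirical_variogram()]).
#' @param kernel_scales candidate Gaussian smoothing scales; default
#'   `c(0.02, 0.05, 0.10, 0.15, 0.20, 0.30)` times the maximum pairwise
#'   distance of valid locations. The ladder should bracket the data's
#'   autocorrelation scale; the fit degrades when no candidate comes close.
#' @param force_fit optional `list(alpha =, beta =, scale =)` overriding
#'   the per-surrogate fit (test hook; with `alpha = 0, beta = 1` the
#'   surrogate is exactly the smoothed permutation, up to the final
#'   rescaling which can be disabled with `rescale = FALSE`).
#' @param rescale rescale each surrogate to the source mean/variance
#'   (default `TRUE`).
#' @return A [null_ensemble()] with framework `"variogram"`; the selected
#'   `kernel_scale`, `alpha`, `beta` and `sse` per surrogate are in
#'   `params$fits`.
#' @export
variogram_null <- function(map, n_null, seed, n_bins = 25L, max_quantile = 0.25,
                           kernel_scales = NULL, force_fit = NULL,
                           rescale = TRUE) {
  if (n_null < 1L) stop_invalid("'n_null' must be >= 1")
  mask <- map$mask
  n_valid <- sum(mask)
  if (n_valid < 3L) stop_insufficient("need >= 3 valid locations")
  coords <- location_coords(map$space)[mask, , drop = FALSE]
  vspace <- point_space(coords)
  x <- map$values[mask]
  mu <- mean(x); sdev <- stats::sd(x)

  ps <- pair_structure(vspace, n_bins = n_bins, max_quantile = max_quantile)
  all_valid <- rep(TRUE, n_valid)
  gamma_orig <- variogram_from_pairs(x, all_valid, ps)$gamma
  if (is.null(kernel_scales)) {
    dmax <- max_pair_distance(vspace)
    kernel_scales <- c(0.02, 0.05, 0.10, 0.15, 0.20, 0.30) * dmax
  }
  kernels <- lapply(kernel_scales, function(s) smoothing_kernel(vspace, s))

  seeds <- derive_seeds(seed, n_null)
  L <- length(map$values)
  out <- matrix(NA_real_, n_null, L)
  fits <- data.frame(kernel_scale = numeric(n_null), alpha = numeric(n_null),
                     beta = numeric(n_null), sse = numeric(n_null))
  for (k in seq_len(n_null)) {
    draws <- with_seed(seeds[k], {
      list(perm = sample.int(n_valid), z = stats::rnorm(n_valid))
    })
    xp <- x[draws$perm]
    best <- NULL
    for (s in seq_along(kernel_scales)) {
      xs <- if (is.null(kernels[[s]])) xp else as.numeric(kernels[[s]] %*% xp)
      if (stats::sd(xs) < 1e-12) next
      if (!is.null(force_fit)) {
        if (!isTRUE(all.equal(kernel_scales[s], force_fit$scale))) next
        cand <- list(alpha = force_fit$alpha, beta = force_fit$beta, sse = 0)
      } else {
        gamma_s <- variogram_from_pairs(xs, all_valid, ps)$gamma
        cand <- fit_variogram(gamma_orig, gamma_s, stats::var(x), stats::var(xs))
        if (is.null(cand)) next
      }
      if (is.null(best) || cand$sse < best$sse) {
        best <- c(cand, list(scale = kernel_scales[s], smoothed = xs))
      }
    }
    if (is.null(best)) {
      stop_numerical("all candidate variogram fits degenerate for surrogate ", k)
    }
    y <- sqrt(abs(best$beta)) * best$smoothed + sqrt(abs(best$alpha)) * draws$z
    if (rescale) y <- (y - mean(y)) / stats::sd(y) * sdev + mu
    row <- rep(NA_real_, L)
    row[mask] <- y
    out[k, ] <- row
    fits[k, ] <- c(best$scale, best$alpha, best$beta, best$sse)
  }
  null_ensemble(out, "variogram", seed,
                params = list(n_null = n_null, n_bins = n_bins,
                              max_quantile = max_quantile,
                              kernel_scales = kernel_scales, fits = fits),
                space_key = space_digest(map$space))
}

# A bare cloud of points with world coordinates; lets the variogram and
# Moran machinery treat "the valid locations of some space" as a space.
point_space <- function(coords) {
  structure(list(coords = coords), class = "point_space")
}
#' @export
n_locations.point_space <- function(space) nrow(space$coords)
#' @export
space_id.point_space <- function(space) sprintf("points(%d)", nrow(space$coords))
#' @export
location_coords.point_space <- function(space) space$coords

max_pair_distance <- function(space) {
  max(cached_chords(space))
}
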