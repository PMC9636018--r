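# Seeded generators of spatially autocorrelated scalar maps, medial-wall
# masks and Voronoi parcellations. Everything statistical in the package is
# testable against these generators, with no external data.

# Session caches for pairwise distance matrices and smoothing kernels,
# keyed by content digest. Dense matrices are fine at the mesh sizes these
# tools target (<= ico5); larger spaces would need a sparse neighbour
# structure instead.
.geom_cache <- new.env(parent = emptyenv())

space_digest <- function(space) {
  key <- paste0("digest_", content_digest(location_coords(space)))
  key
}

cached_chords <- function(space) {
  key <- paste0("D_", space_digest(space))
  d <- .geom_cache[[key]]
  if (is.null(d)) {
    d <- pairwise_chords(location_coords(space))
    .geom_cache[[key]] <- d
  }
  d
}

# Row-normalized Gaussian kernel over chord (or world) distances, truncated
# at 3 * scale. scale = 0 degenerates to the identity (no smoothing).
smoothing_kernel <- function(space, scale) {
  if (scale < 0) stop_invalid("'smoothing_scale' must be >= 0")
  if (scale == 0) return(NULL)
  key <- paste0("K_", space_digest(space), "_", format(scale, digits = 17))
  k <- .geom_cache[[key]]
  if (is.null(k)) {
    d <- cached_chords(space)
    k <- exp(-d^2 / (2 * scale^2))
    k[d > 3 * scale] <- 0
    k <- k / rowSums(k)
    .geom_cache[[key]] <- k
  }
  k
}

smooth_field <- function(space, x, scale) {
  k <- smoothing_kernel(space, scale)
  if (is.null(k)) return(x)
  as.numeric(k %*% x)
}

standardize <- function(x) {
  (x - mean(x)) / stats::sd(x)
}

#' Specification of a synthetic Gaussian random field
#'
#' @param smoothing_scale Gaussian kernel scale in chord-distance units
#'   (unit-sphere radius = 1); 0 gives spatially independent noise.
#' @param target_r desired expected Pearson correlation for paired maps,
#'   in `[-1, 1]`.
#' @param seed integer seed.
#' @return An object of class `grf_spec`.
#' @export
grf_spec <- function(smoothing_scale = 0.3, target_r = 0, seed = 1L) {
  if (!is_scalar_number(smoothing_scale) || smoothing_scale < 0) {
    stop_invalid("'smoothing_scale' must be a nonnegative number")
  }
  if (!is_scalar_number(target_r) || abs(target_r) > 1) {
    stop_invalid("'target_r' must be in [-1, 1]")
  }
  structure(list(smoothing_scale = smoothing_scale, target_r = target_r,
                 seed = assert_seed(seed)),
            class = "grf_spec")
}

#' Sample a spatially autocorrelated map
#'
#' Draws white Gaussian noise over the valid locations of a space, smooths
#' it with a Gaussian kernel of scale `spec$smoothing_scale` over chord
#' (surface) or world-mm (volume) distances, and standardizes the result to
#' mean 0, variance 1. Larger scales give stronger spatial autocorrelation
#' (larger Moran's I, longer variogram range). Deterministic given the seed.
#'
#' @param space a [spherical_mesh()] or [volume_grid()].
#' @param spec a [grf_spec()].
#' @param mask optional logical validity mask (default: all locations valid).
#' @return A [scalar_map()].
#' @export
sample_grf <- function(space, spec, mask = NULL) {
  L <- n_locations(space)
  if (is.null(mask)) mask <- rep(TRUE, L)
  if (!any(mask)) stop_invalid("mask excludes every location")
  z <- with_seed(spec$seed, stats::rnorm(L))
  x <- smooth_field(space, z, spec$smoothing_scale)
  values <- rep(NA_real_, L)
  values[mask] <- standardize(x[mask])
  scalar_map(values, space, mask = mask, name = "grf")
}

#' Sample a pair of maps with a known true correlation
#'
#' Generates two maps with identical autocorrelation structure whose
#' expected Pearson correlation is `spec$target_r`: a shared smoothed field
#' `u` and an independent one `v` are mixed as
#' `r * u + sqrt(1 - r^2) * v`. Used to calibrate null models (type-I
#' error at `target_r = 0`, power at `target_r > 0`).
#'
#' @inheritParams sample_grf
#' @return A list of two [scalar_map()]s.
#' @export
sample_grf_pair <- function(space, spec, mask = NULL) {
  L <- n_locations(space)
  if (is.null(mask)) mask <- rep(TRUE, L)
  if (!any(mask)) stop_invalid("mask excludes every location")
  noise <- with_seed(spec$seed, matrix(stats::rnorm(2L * L), ncol = 2L))
  u <- smooth_field(space, noise[, 1L], spec$smoothing_scale)
  v <- smooth_field(space, noise[, 2L], spec$smoothing_scale)
  r <- spec$target_r
  u_std <- standardize(u[mask])
  v_std <- standardize(v[mask])
  a <- rep(NA_real_, L); b <- rep(NA_real_, L)
  a[mask] <- u_std
  b[mask] <- standardize(r * u_std + sqrt(1 - r^2) * v_std)
  list(scalar_map(a, space, mask = mask, name = "grf_a"),
       scalar_map(b, space, mask = mask, name = "grf_b"))
}

#' Sample a synthetic medial wall
#'
#' Marks a connected spherical-cap region of about `fraction` of the
#' vertices as invalid, centred on a seeded random vertex. Emulates the
#' medial wall of cortical meshes, for which most brain maps contain no
#' data.
#'
#' @param mesh a [spherical_mesh()].
#' @param fraction fraction of vertices to invalidate, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return Logical mask, `TRUE` = valid data.
#' @export
sample_medial_wall <- function(mesh, fraction, seed = 1L) {
  if (!is_scalar_number(fraction) || fraction < 0 || fraction >= 0.5) {
    stop_invalid("'fraction' must be in [0, 0.5)")
  }
  L <- n_vertices(mesh)
  mask <- rep(TRUE, L)
  n_invalid <- round(fraction * L)
  if (n_invalid == 0L) return(mask)
  center <- with_seed(seed, sample.int(L, 1L))
  d <- sqrt(colSums((t(mesh$vertices) - mesh$vertices[center, ])^2))
  cap <- order(d)[seq_len(n_invalid)]
  mask[cap] <- FALSE
  mask
}

#' Sample a Voronoi parcellation
#'
#' Assigns every vertex to the nearest (chord distance) of `n_parcels`
#' seeded random centre vertices; ties go to the lowest-id centre. Every
#' parcel contains at least its own centre.
#'
#' @param mesh a [spherical_mesh()].
#' @param n_parcels number of parcels, in `[1, L/3]`.
#' @param seed integer seed.
#' @return A [parcellation()] with labels `1..n_parcels`.
#' @export
sample_parcellation <- function(mesh, n_parcels, seed = 1L) {
  L <- n_vertices(mesh)
  if (!is_scalar_number(n_parcels) || n_parcels < 1 || n_parcels > L / 3) {
    stop_invalid("'n_parcels' must be in [1, ", floor(L / 3), "] for this mesh")
  }
  n_parcels <- as.integer(n_parcels)
  centers <- with_seed(seed, sample.int(L, n_parcels))
  nn <- nearest_index(mesh$vertices[centers, , drop = FALSE], mesh$vertices)
  parcellation(nn$index, mesh)
}
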