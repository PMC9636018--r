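# Spatial permutation ("spin") null models. A random rotation of the
# sphere is applied to the mesh coordinates and every vertex takes the
# value of the nearest rotated vertex, destroying the map's topography
# while preserving its spatial autocorrelation. Rotations are drawn for
# one hemisphere and mirrored across the mid-sagittal plane for the other,
# so left/right surrogates stay anatomically congruent.

#' Sample a Haar-uniform rotation
#'
#' Draws a rotation matrix uniformly over SO(3) (QR decomposition of a
#' Gaussian matrix with sign correction; a reflection is folded back into
#' the rotation group by negating one column). The mirrored rotation for
#' the opposite hemisphere is the conjugation `F R F` with
#' `F = diag(-1, 1, 1)`, i.e. reflection about the mid-sagittal plane,
#' which preserves the anterior-posterior axis.
#'
#' @param seed integer seed.
#' @return A list with elements `R`, `R_mirror` (3x3 rotation matrices)
#'   and `seed`, of class `rotation_sample`.
#' @export
sample_rotation <- function(seed) {
  g <- with_seed(seed, matrix(stats::rnorm(9L), 3L, 3L))
  qr_g <- qr(g)
  q <- qr.Q(qr_g)
  # Sign correction makes Q Haar on O(3); negating a fixed column maps the
  # reflection component back onto SO(3) without breaking invariance.
  q <- q %*% diag(sign(diag(qr.R(qr_g))))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  f <- diag(c(-1, 1, 1))
  structure(list(R = q, R_mirror = f %*% q %*% f, seed = assert_seed(seed)),
            class = "rotation_sample")
}

rotation_angle <- function(R) {
  acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
}

# Spin permutation index for one rotation: perm[i] = index of the rotated
# vertex closest to original vertex i (ties: lowest index). Unit vectors
# make "closest" equal to "largest dot product", which is a single matrix
# product.
spin_permutation <- function(vertices, R) {
  rotated <- vertices %*% R
  max.col(vertices %*% t(rotated), ties.method = "first")
}

#' Precompute spin permutation indices
#'
#' The permutation induced by a rotation depends only on the mesh, not on
#' the map, so a batch of analyses on one mesh can reuse one index matrix
#' (the expensive part of the spin test). Column `k` holds, for each
#' vertex, the index of the source vertex it receives under rotation `k`.
#'
#' @param mesh a [spherical_mesh()].
#' @param n_null number of rotations.
#' @param seed integer seed.
#' @param mirror use the mirrored rotations (`R_mirror`), as appropriate
#'   for the opposite hemisphere of a pair sharing `seed`.
#' @return Integer `L x n_null` matrix.
#' @export
spin_indices <- function(mesh, n_null, seed, mirror = FALSE) {
  rotations <- lapply(derive_seeds(seed, n_null), sample_rotation)
  vapply(rotations, function(r) {
    spin_permutation(mesh$vertices, if (mirror) r$R_mirror else r$R)
  }, integer(n_vertices(mesh)))
}

#' Null ensembles
#'
#' Container for `n_null` surrogate maps: an `n_null x L` matrix of values
#' (masked or unassignable entries `NA`), the generating framework, seed,
#' parameters and a content digest that makes the ensemble regenerable and
#' cacheable.
#'
#' @param surrogates numeric `n_null x L` matrix.
#' @param framework one of `"spin_vertex"`, `"spin_parcel_discard"`,
#'   `"spin_parcel_ignore"`, `"spin_parcel_nearest"`, `"variogram"`,
#'   `"moran"`.
#' @param seed integer seed used to generate the ensemble.
#' @param params named list of generator parameters (provenance).
#' @param space_key digest of the generating space (provenance).
#' @return An object of class `null_ensemble`.
#' @export
null_ensemble <- function(surrogates, framework, seed, params = list(),
                          space_key = "") {
  framework <- match.arg(framework, c("spin_vertex", "spin_parcel_discard",
                                      "spin_parcel_ignore", "spin_parcel_nearest",
                                      "variogram", "moran"))
  surrogates <- as.matrix(surrogates)
  cache_key <- content_digest(list(space_key, framework, nrow(surrogates),
                                   seed, params))
  structure(list(surrogates = surrogates, framework = framework,
                 seed = assert_seed(seed), params = params,
                 cache_key = cache_key),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d surrogates x %d locations, framework '%s', seed %d\n",
              nrow(x$surrogates), ncol(x$surrogates), x$framework, x$seed))
  invisible(x)
}

#' Vertex-level spin permutation nulls
#'
#' For each of `n_null` Haar-uniform rotations, every vertex receives the
#' value of the nearest rotated vertex. When a second hemisphere is given
#' its rotations are the mirrored versions of the first hemisphere's, and
#' the surrogate is the (first, other) concatenation. Vertices whose
#' assigned source vertex is masked (medial wall) become `NA`: data are
#' neither invented nor silently dropped.
#'
#' @param map a [scalar_map()] on `mesh`.
#' @param mesh the [spherical_mesh()] the map lives on.
#' @param n_null number of surrogates.
#' @param seed integer seed.
#' @param mesh_other,map_other optional opposite-hemisphere mesh and map.
#' @param rotations optional list of [sample_rotation()] objects (e.g.
#'   forced identity rotations in tests); overrides seeded generation.
#' @param indices optional precomputed [spin_indices()] matrix for `mesh`
#'   (and `indices_other` for `mesh_other`); skips the rotation search.
#' @param indices_other see `indices`.
#' @return A [null_ensemble()] with framework `"spin_vertex"`.
#' @export
spin_vertex <- function(map, mesh, n_null, seed, mesh_other = NULL,
                        map_other = NULL, rotations = NULL, indices = NULL,
                        indices_other = NULL) {
  if (!any(map$mask)) stop_invalid("map is fully masked")
  two_hemi <- !is.null(mesh_other)
  if (two_hemi && is.null(map_other)) {
    stop_invalid("'map_other' is required when 'mesh_other' is given")
  }
  if (is.null(indices)) {
    if (n_null < 1L) stop_invalid("'n_null' must be >= 1")
    if (is.null(rotations)) {
      rotations <- lapply(derive_seeds(seed, n_null), sample_rotation)
    }
    indices <- vapply(rotations, function(r) {
      spin_permutation(mesh$vertices, r$R)
    }, integer(n_vertices(mesh)))
    if (two_hemi) {
      indices_other <- vapply(rotations, function(r) {
        spin_permutation(mesh_other$vertices, r$R_mirror)
      }, integer(n_vertices(mesh_other)))
    }
  } else if (two_hemi && is.null(indices_other)) {
    stop_invalid("'indices_other' is required with precomputed 'indices'")
  }
  n_null <- ncol(indices)
  v1 <- map$values
  L1 <- length(v1)
  L <- if (two_hemi) L1 + length(map_other$values) else L1
  out <- matrix(NA_real_, n_null, L)
  for (k in seq_len(n_null)) {
    out[k, seq_len(L1)] <- v1[indices[, k]]
    if (two_hemi) {
      out[k, (L1 + 1L):L] <- map_other$values[indices_other[, k]]
    }
  }
  null_ensemble(out, "spin_vertex", seed,
                params = list(n_null = n_null, two_hemisphere = two_hemi),
                space_key = space_digest(mesh))
}

parcel_centroids <- function(parc) {
  ids <- parcel_ids(parc)
  coords <- location_coords(parc$space)
  t(vapply(ids, function(id) {
    colMeans(coords[parc$labels == id, , drop = FALSE])
  }, numeric(3)))
}

#' Parcellated spin permutation nulls
#'
#' Projects per-parcel values to vertices, applies vertex-level spins, and
#' re-aggregates to parcels by the vertex mean. The three strategies differ
#' in how they treat parcels whose rotated sources land on the medial wall:
#' `"discard"` leaves such parcels `NA` when every contributing vertex is
#' missing; `"ignore"` removes medial-wall vertices from the mesh before
#' rotating, so no missingness is ever introduced; `"nearest"` fills `NA`
#' parcels with the value of the nearest (centroid chord distance)
#' non-`NA` parcel.
#'
#' @param values numeric vector of per-parcel values, indexed by parcel id
#'   `1..K`.
#' @param parc a [parcellation()] on a [spherical_mesh()].
#' @param strategy `"discard"`, `"ignore"` or `"nearest"`.
#' @param n_null number of surrogates.
#' @param seed integer seed.
#' @param mask optional vertex validity mask (`FALSE` = medial wall).
#' @param rotations optional list of [sample_rotation()] objects (test hook).
#' @return A [null_ensemble()] of `n_null x K` per-parcel surrogates.
#' @export
spin_parcellated <- function(values, parc, strategy = c("discard", "ignore", "nearest"),
                             n_null, seed, mask = NULL, rotations = NULL) {
  strategy <- match.arg(strategy)
  mesh <- parc$space
  if (!inherits(mesh, "spherical_mesh")) {
    stop_invalid("parcellated spins require a parcellation on a spherical_mesh")
  }
  ids <- parcel_ids(parc)
  K <- length(ids)
  if (length(values) != K) {
    stop_invalid("'values' must have one entry per parcel (", K, ")")
  }
  if (any(tabulate(parc$labels, nbins = max(ids))[ids] == 0L)) {
    stop_invalid("every parcel must contain at least one vertex")
  }
  L <- n_vertices(mesh)
  if (is.null(mask)) mask <- rep(TRUE, L)
  if (is.null(rotations)) {
    rotations <- lapply(derive_seeds(seed, n_null), sample_rotation)
  }
  n_null <- length(rotations)

  # Project parcel values to vertices; background and medial wall are NA.
  vert_values <- rep(NA_real_, L)
  nz <- parc$labels > 0L
  vert_values[nz] <- values[match(parc$labels[nz], ids)]
  vert_values[!mask] <- NA_real_

  if (strategy == "ignore") {
    keep <- which(mask)
    verts <- mesh$vertices[keep, , drop = FALSE]
    labels <- parc$labels[keep]
    src_values <- vert_values[keep]
  } else {
    verts <- mesh$vertices
    labels <- parc$labels
    src_values <- vert_values
  }
  group <- factor(labels, levels = ids)

  out <- matrix(NA_real_, n_null, K)
  for (k in seq_len(n_null)) {
    perm <- spin_permutation(verts, rotations[[k]]$R)
    spun <- src_values[perm]
    agg <- tapply(spun, group, function(v) mean(v, na.rm = TRUE))
    out[k, ] <- as.numeric(agg)
  }
  out[is.nan(out)] <- NA_real_

  if (strategy == "nearest") {
    cent <- parcel_centroids(parc)
    for (k in seq_len(n_null)) {
      missing <- which(is.na(out[k, ]))
      present <- which(!is.na(out[k, ]))
      if (length(missing) > 0L && length(present) > 0L) {
        for (m in missing) {
          d2 <- colSums((t(cent[present, , drop = FALSE]) - cent[m, ])^2)
          out[k, m] <- out[k, present[which.min(d2)]]
        }
      }
    }
  }

  null_ensemble(out, paste0("spin_parcel_", strategy), seed,
                params = list(n_null = n_null, strategy = strategy,
                              n_parcels = K),
                space_key = space_digest(mesh))
}

#' Cache or retrieve a null ensemble
#'
#' Ensembles are expensive; they are persisted as RDS keyed by their
#' content digest with a JSON provenance sidecar. A cache hit is verified
#' by digest before reuse.
#'
#' @param ensemble a [null_ensemble()].
#' @param cache_dir directory for cached ensembles.
#' @return `cache_ensemble()` returns the RDS path invisibly;
#'   `fetch_ensemble()` returns the ensemble or `NULL` on a miss.
#' @export
cache_ensemble <- function(ensemble, cache_dir) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(cache_dir, paste0(ensemble$cache_key, ".rds"))
  saveRDS(ensemble, path)
  sidecar <- list(framework = ensemble$framework, seed = ensemble$seed,
                  n_null = nrow(ensemble$surrogates),
                  params = ensemble$params, cache_key = ensemble$cache_key)
  jsonlite::write_json(sidecar, sub("\\.rds$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param cache_key digest key of the ensemble to fetch.
#' @rdname cache_ensemble
#' @export
fetch_ensemble <- function(cache_key, cache_dir) {
  path <- file.path(cache_dir, paste0(cache_key, ".rds"))
  if (!file.exists(path)) return(NULL)
  ens <- readRDS(path)
  if (!identical(ens$cache_key, cache_key)) return(NULL)
  ens
}
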