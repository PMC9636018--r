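# Moving maps between mesh resolutions and aggregating them to parcels.
# Continuous data travel by nearest-neighbour / k-NN lookup only; when two
# maps must share a space, the higher-resolution one is brought down to the
# lower-resolution space so no data are artificially upsampled.

#' Apply a nearest-neighbour correspondence
#'
#' Each target location takes the value of its assigned source location;
#' masked sources propagate missingness.
#'
#' @param map a [scalar_map()] on the table's source space.
#' @param table a [correspondence_table()].
#' @param target_space the space the table maps onto.
#' @return A [scalar_map()] on `target_space`.
#' @export
apply_correspondence <- function(map, table, target_space) {
  if (max(table$source_index) > length(map$values)) {
    stop_invalid("correspondence table indexes beyond the source map")
  }
  if (length(table$source_index) != n_locations(target_space)) {
    stop_invalid("correspondence table does not match the target space")
  }
  scalar_map(map$values[table$source_index], target_space, name = map$name)
}

#' k-nearest-neighbour interpolation between meshes
#'
#' Each target vertex becomes the unweighted mean of its `k` nearest valid
#' source values (chord distance); if fewer than `k` valid sources exist on
#' the whole mesh, the available ones are used; a fully invalid source map
#' yields `NA`. With `k = 1` this reduces to
#' [apply_correspondence()] over [nearest_source()].
#'
#' @param map a [scalar_map()] on `mesh_src`.
#' @param mesh_src,mesh_tgt source and target [spherical_mesh()]es.
#' @param k neighbour count (>= 1).
#' @return A [scalar_map()] on `mesh_tgt`.
#' @export
knn_interpolate <- function(map, mesh_src, mesh_tgt, k = 3L) {
  if (!is_scalar_number(k) || k < 1L) stop_invalid("'k' must be >= 1")
  k <- as.integer(k)
  valid <- which(map$mask)
  n_tgt <- n_vertices(mesh_tgt)
  if (length(valid) == 0L) {
    return(scalar_map(rep(NA_real_, n_tgt), mesh_tgt, name = map$name))
  }
  src <- t(mesh_src$vertices[valid, , drop = FALSE])
  vals <- map$values[valid]
  kk <- min(k, length(valid))
  out <- numeric(n_tgt)
  for (j in seq_len(n_tgt)) {
    d2 <- colSums((src - mesh_tgt$vertices[j, ])^2)
    nb <- order(d2)[seq_len(kk)]
    out[j] <- mean(vals[nb])
  }
  scalar_map(out, mesh_tgt, name = map$name)
}

mesh_resolution <- function(map) {
  sum(map$mask)
}

#' Bring two maps into a common space
#'
#' When the maps live on different meshes the higher-resolution map
#' (larger valid-vertex count; ties favour the first argument's space) is
#' resampled to the lower-resolution mesh by nearest-neighbour lookup, so
#' no data are artificially upsampled. An explicit `target` mesh overrides
#' the rule in either direction. Surface-to-volume resampling of
#' continuous data is refused.
#'
#' @param map_a,map_b [scalar_map()]s on [spherical_mesh()] spaces.
#' @param target optional [spherical_mesh()] overriding the
#'   lower-resolution rule.
#' @return A list of the two [scalar_map()]s in the common space.
#' @export
align_pair <- function(map_a, map_b, target = NULL) {
  sa <- map_a$space; sb <- map_b$space
  if (inherits(sa, "volume_grid") || inherits(sb, "volume_grid")) {
    if (inherits(sa, "volume_grid") && inherits(sb, "volume_grid")) {
      if (!identical(space_digest(sa), space_digest(sb))) {
        stop_unsupported("no correspondence derivable between distinct volume grids")
      }
      return(list(map_a, map_b))
    }
    stop_unsupported(
      "surface-to-volume resampling of continuous data is not supported; ",
      "re-express both maps on a surface mesh")
  }
  to_mesh <- function(map, mesh) {
    if (identical(space_digest(map$space), space_digest(mesh))) return(map)
    apply_correspondence(map, nearest_source(map$space, mesh), mesh)
  }
  if (!is.null(target)) {
    return(list(to_mesh(map_a, target), to_mesh(map_b, target)))
  }
  if (identical(space_digest(sa), space_digest(sb))) {
    return(list(map_a, map_b))
  }
  if (mesh_resolution(map_b) < mesh_resolution(map_a)) {
    list(to_mesh(map_a, sb), map_b)
  } else {
    list(map_a, to_mesh(map_b, sa))
  }
}

#' Aggregate a map to parcels
#'
#' Per-parcel mean over valid locations; background (label 0) is ignored
#' and parcels with no valid locations yield `NA`.
#'
#' @param map a [scalar_map()].
#' @param parc a [parcellation()] on the same space.
#' @return Named numeric vector of parcel means, names = parcel ids.
#' @export
parcellate_map <- function(map, parc) {
  if (length(parc$labels) != length(map$values)) {
    stop_invalid("parcellation and map live on spaces of different size")
  }
  ids <- parcel_ids(parc)
  use <- map$mask & parc$labels > 0L
  group <- factor(parc$labels[use], levels = ids)
  agg <- tapply(map$values[use], group, mean)
  out <- as.numeric(agg)
  out[is.nan(out)] <- NA_real_
  names(out) <- ids
  out
}
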