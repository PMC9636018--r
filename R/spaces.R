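#' Scalar maps over surface vertices or voxels
#'
#' A `scalar_map` holds one value per location of its space together with a
#' validity mask. `mask = FALSE` marks locations with no data (the medial
#' wall of cortical meshes, out-of-brain voxels); such locations carry `NA`
#' values and are excluded from every statistic in the package.
#'
#' @param values numeric vector, one value per location.
#' @param space a [spherical_mesh()] or [volume_grid()].
#' @param mask logical vector (`TRUE` = valid). Defaults to `!is.na(values)`.
#' @param name free-text map name.
#' @return An object of class `scalar_map`.
#' @export
scalar_map <- function(values, space, mask = NULL, name = "") {
  L <- n_locations(space)
  values <- as.numeric(values)
  if (length(values) != L) {
    stop_format("map has ", length(values), " values but its space has ", L,
                " locations")
  }
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.logical(mask)
  if (length(mask) != L) stop_invalid("'mask' length must equal location count")
  mask[is.na(mask)] <- FALSE
  mask <- mask & !is.na(values)
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, space = space, name = name),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf("scalar_map '%s': %d locations (%d valid) on %s\n",
              x$name, length(x$values), sum(x$mask), space_id(x$space)))
  invisible(x)
}

n_locations <- function(space) UseMethod("n_locations")
#' @export
n_locations.spherical_mesh <- function(space) nrow(space$vertices)
#' @export
n_locations.volume_grid <- function(space) sum(space$mask)

space_id <- function(space) UseMethod("space_id")
#' @export
space_id.spherical_mesh <- function(space) {
  sprintf("mesh '%s' (%s)", space$resolution_id, space$hemisphere)
}
#' @export
space_id.volume_grid <- function(space) {
  sprintf("volume %s", paste(space$shape, collapse = "x"))
}

# World-mm coordinates of every valid location of a space. This is the
# single geometry accessor the variogram and Moran machinery relies on, and
# what makes those null models space-agnostic.
location_coords <- function(space) UseMethod("location_coords")
#' @export
location_coords.spherical_mesh <- function(space) space$vertices
#' @export
location_coords.volume_grid <- function(space) {
  ijk <- which(array(space$mask, dim = space$shape), arr.ind = TRUE)
  vox <- cbind(ijk - 1, 1) # 0-based voxel indices, homogeneous
  world <- vox %*% t(space$affine)
  world[, 1:3, drop = FALSE]
}

#' Volumetric grids
#'
#' Shape, voxel-to-world affine and a voxel validity mask. Scalar maps on a
#' `volume_grid` store one value per *masked-in* voxel, in the column-major
#' order of `which(mask)`; world coordinates of voxel centers are
#' `affine %*% c(i, j, k, 1)` with 0-based indices.
#'
#' @param shape integer vector of 3 positive extents.
#' @param affine numeric 4x4 invertible voxel-to-world matrix (mm).
#' @param mask logical array of dimension `shape` (default all `TRUE`).
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, affine = diag(4), mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop_invalid("'shape' must be 3 positive integers")
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop_invalid("'affine' must be 4x4")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < 1e-12) {
    stop_format("affine is not invertible (determinant ", format(det_a), ")")
  }
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  mask <- array(as.logical(mask), dim = shape)
  structure(list(shape = shape, affine = affine, mask = mask),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid %s: %d voxels in mask\n",
              paste(x$shape, collapse = "x"), sum(x$mask)))
  invisible(x)
}

#' Parcellations
#'
#' Integer labels over the locations of a space; 0 is background and is
#' ignored by every aggregation. `id_map` records, for each parcel id, the
#' hemisphere and original id it came from, which makes relabeling
#' invertible.
#'
#' @param labels non-negative integer vector, one label per location.
#' @param space the space the labels live on.
#' @param id_map data.frame with columns `id`, `hemisphere`, `original_id`,
#'   `name`; autogenerated when omitted.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, space, id_map = NULL) {
  labels <- as.integer(labels)
  if (any(labels < 0L, na.rm = TRUE)) stop_invalid("parcel labels must be >= 0")
  labels[is.na(labels)] <- 0L
  if (length(labels) != n_locations(space)) {
    stop_format("parcellation has ", length(labels), " labels but its space has ",
                n_locations(space), " locations")
  }
  ids <- sort(unique(labels[labels > 0L]))
  if (is.null(id_map)) {
    hemi <- if (inherits(space, "spherical_mesh")) space$hemisphere else "both"
    id_map <- data.frame(id = ids, hemisphere = rep(hemi, length(ids)),
                         original_id = ids,
                         name = sprintf("parcel_%d", ids),
                         stringsAsFactors = FALSE)
  }
  if (!all(ids %in% id_map$id)) {
    stop_invalid("every non-zero label must have an id_map row")
  }
  structure(list(labels = labels, space = space, id_map = id_map),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d parcels over %d locations (%d background)\n",
              length(unique(x$labels[x$labels > 0L])), length(x$labels),
              sum(x$labels == 0L)))
  invisible(x)
}

parcel_ids <- function(parc) sort(unique(parc$labels[parc$labels > 0L]))

#' Relabel two hemispheric parcellations consecutively
#'
#' Surface parcellations are commonly distributed as separate left/right
#' files reusing the same ids in both hemispheres. This remaps them to a
#' single consecutive id range `1..K` (left ids first, then right ids
#' offset), keeping 0 as background and recording the original
#' (hemisphere, id) of every new id so the operation is invertible.
#'
#' @param left,right [parcellation()] objects for the two hemispheres.
#' @return A list with elements `left` and `right` (relabeled
#'   [parcellation()]s sharing one `id_map`) and `id_map`.
#' @export
relabel_consecutive <- function(left, right) {
  ids_l <- parcel_ids(left)
  ids_r <- parcel_ids(right)
  new_l <- seq_along(ids_l)
  new_r <- length(ids_l) + seq_along(ids_r)
  id_map <- data.frame(
    id = c(new_l, new_r),
    hemisphere = rep(c("left", "right"), c(length(ids_l), length(ids_r))),
    original_id = c(ids_l, ids_r),
    name = c(sprintf("L_%d", ids_l), sprintf("R_%d", ids_r)),
    stringsAsFactors = FALSE
  )
  remap <- function(labels, old_ids, new_ids) {
    out <- integer(length(labels))
    out[labels > 0L] <- new_ids[match(labels[labels > 0L], old_ids)]
    out
  }
  list(
    left = parcellation(remap(left$labels, ids_l, new_l), left$space, id_map),
    right = parcellation(remap(right$labels, ids_r, new_r), right$space, id_map),
    id_map = id_map
  )
}

#' Restore per-hemisphere original labels
#'
#' Inverse of [relabel_consecutive()] for one hemisphere.
#'
#' @param parc a relabeled [parcellation()].
#' @param hemisphere `"left"` or `"right"`.
#' @return A [parcellation()] with the original ids of that hemisphere.
#' @export
restore_labels <- function(parc, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  rows <- parc$id_map[parc$id_map$hemisphere == hemisphere, ]
  out <- integer(length(parc$labels))
  nz <- parc$labels > 0L
  out[nz] <- rows$original_id[match(parc$labels[nz], rows$id)]
  parcellation(out, parc$space)
}
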