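#' Spherical surface meshes
#'
#' A `spherical_mesh` is a triangulated representation of one cortical
#' hemisphere projected to the unit sphere: an `L x 3` matrix of vertex
#' coordinates (every row has norm 1), a `T x 3` integer matrix of faces,
#' a hemisphere tag and a free-text resolution tag. It is the coordinate
#' matrix that spatial permutation ("spin") null models rotate.
#'
#' @param vertices numeric `L x 3` matrix of unit-norm coordinates.
#' @param faces integer `T x 3` matrix of 1-based vertex indices.
#' @param hemisphere `"left"` or `"right"`.
#' @param resolution_id free-text tag, e.g. `"ico4"`.
#' @return An object of class `spherical_mesh`.
#' @export
spherical_mesh <- function(vertices, faces, hemisphere = c("left", "right"),
                           resolution_id = "custom") {
  hemisphere <- match.arg(hemisphere)
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3L)
  if (ncol(vertices) != 3L) stop_invalid("'vertices' must have 3 columns")
  nrm <- sqrt(rowSums(vertices^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    stop_invalid("all vertices must lie on the unit sphere (|norm - 1| <= 1e-9)")
  }
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop_invalid("face indices out of vertex range")
  }
  structure(
    list(vertices = vertices, faces = faces, hemisphere = hemisphere,
         resolution_id = resolution_id),
    class = "spherical_mesh"
  )
}

#' @export
print.spherical_mesh <- function(x, ...) {
  cat(sprintf("spherical_mesh '%s' (%s hemisphere): %d vertices, %d faces\n",
              x$resolution_id, x$hemisphere, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

n_vertices <- function(mesh) nrow(mesh$vertices)

# Base icosahedron: 12 vertices from the three golden-ratio rectangles,
# normalized to the unit sphere. Pure arithmetic, hence bit-identical
# across runs and platforms with IEEE doubles.
icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6),  c(1, 6, 2),   c(1, 2, 8),   c(1, 8, 11),  c(1, 11, 12),
    c(2, 6, 10),  c(6, 12, 5),  c(12, 11, 3), c(11, 8, 7),  c(8, 2, 9),
    c(4, 10, 5),  c(4, 5, 3),   c(4, 3, 7),   c(4, 7, 9),   c(4, 9, 10),
    c(5, 10, 6),  c(3, 5, 12),  c(7, 3, 11),  c(9, 7, 8),   c(10, 9, 2)
  )
  list(vertices = v, faces = f)
}

subdivide_once <- function(vertices, faces) {
  n <- nrow(vertices)
  # Edge midpoints are deduplicated via a key on the (sorted) endpoint pair;
  # new vertices are appended after the parents in first-encountered order,
  # so every subdivision level contains the previous level's vertices as a
  # bitwise-identical prefix.
  midpoint_env <- new.env(hash = TRUE, parent = emptyenv())
  next_index <- n
  new_vertices <- vector("list", 3L * nrow(faces))
  n_new <- 0L
  midpoint <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    idx <- midpoint_env[[key]]
    if (!is.null(idx)) return(idx)
    m <- (vertices[i, ] + vertices[j, ]) / 2
    m <- m / sqrt(sum(m^2))
    next_index <<- next_index + 1L
    n_new <<- n_new + 1L
    new_vertices[[n_new]] <<- m
    midpoint_env[[key]] <- next_index
    next_index
  }
  new_faces <- matrix(0L, nrow = 4L * nrow(faces), ncol = 3L)
  for (t in seq_len(nrow(faces))) {
    a <- faces[t, 1L]; b <- faces[t, 2L]; c <- faces[t, 3L]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    new_faces[4L * t - 3L, ] <- c(a, ab, ca)
    new_faces[4L * t - 2L, ] <- c(b, bc, ab)
    new_faces[4L * t - 1L, ] <- c(c, ca, bc)
    new_faces[4L * t, ] <- c(ab, bc, ca)
  }
  list(
    vertices = rbind(vertices, do.call(rbind, new_vertices[seq_len(n_new)])),
    faces = new_faces
  )
}

#' Build an icosphere mesh
#'
#' Recursively subdivides an icosahedron `subdivisions` times, projecting
#' each new vertex to the unit sphere. The vertex count at subdivision `s`
#' is `10 * 4^s + 2`. Construction is deterministic: repeated calls return
#' bit-identical meshes, and the vertices of level `s` are a prefix of the
#' vertices of level `s + 1`.
#'
#' @param subdivisions integer in `[0, 7]`.
#' @inheritParams spherical_mesh
#' @return A [spherical_mesh()].
#' @examples
#' mesh <- build_icosphere(2)
#' nrow(mesh$vertices) # 162
#' @export
build_icosphere <- function(subdivisions, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (!is_scalar_number(subdivisions) || subdivisions != round(subdivisions) ||
      subdivisions < 0 || subdivisions > 7) {
    stop_invalid("'subdivisions' must be an integer in [0, 7]")
  }
  m <- icosahedron()
  s <- as.integer(subdivisions)
  for (k in seq_len(s)) m <- subdivide_once(m$vertices, m$faces)
  spherical_mesh(m$vertices, m$faces, hemisphere,
                 resolution_id = paste0("ico", s))
}

#' Chord distance between two vertices
#'
#' Straight-line (Euclidean) distance between unit-sphere coordinates.
#' Chord distance is monotone in geodesic distance on a sphere, so it is
#' used everywhere a distance is needed (nearest-neighbour queries,
#' variogram binning, smoothing kernels).
#'
#' @param mesh a [spherical_mesh()].
#' @param i,j vertex indices (1-based).
#' @return Nonnegative scalar; 2 for antipodal vertices.
#' @export
chord_distance <- function(mesh, i, j) {
  L <- n_vertices(mesh)
  if (any(c(i, j) < 1L) || any(c(i, j) > L)) stop_invalid("vertex index out of range")
  sqrt(sum((mesh$vertices[i, ] - mesh$vertices[j, ])^2))
}

# Full pairwise chord distance matrix (dense; intended for meshes <= ico5).
pairwise_chords <- function(coords) {
  as.matrix(stats::dist(coords, method = "euclidean"))
}

# Undirected edge list (2-column matrix, i < j) from the triangulation.
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  unique(e)
}

# TRUE when every edge is shared by exactly two faces (closed surface).
is_closed_mesh <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1L, 2L)], f[, c(2L, 3L)], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  all(table(key) == 2L)
}

#' Correspondence tables between meshes
#'
#' A `correspondence_table` assigns to every target location the index of a
#' source location, recording the chord distance of each assignment. It is
#' the serializable unit of nearest-neighbour resampling.
#'
#' @param source_index integer vector, one source index per target location.
#' @param distances numeric vector of assignment chord distances.
#' @param source_id,target_id free-text space tags (provenance).
#' @return An object of class `correspondence_table`.
#' @export
correspondence_table <- function(source_index, distances,
                                 source_id = "", target_id = "") {
  if (length(source_index) != length(distances)) {
    stop_invalid("'source_index' and 'distances' must have equal length")
  }
  structure(
    list(source_index = as.integer(source_index), distances = as.numeric(distances),
         source_id = source_id, target_id = target_id),
    class = "correspondence_table"
  )
}

#' @export
print.correspondence_table <- function(x, ...) {
  cat(sprintf("correspondence_table: %d target locations <- '%s' (max distance %.4g)\n",
              length(x$source_index), x$source_id, max(x$distances)))
  invisible(x)
}

# Nearest source vertex for each row of `target_coords`; ties broken by the
# lowest source index. Distances are computed by direct subtraction (not the
# expanded |a|^2+|b|^2-2ab form) so results agree bitwise with a brute-force
# scan even at exact geometric ties.
nearest_index <- function(source_coords, target_coords) {
  st <- t(source_coords)
  n_tgt <- nrow(target_coords)
  idx <- integer(n_tgt)
  dst <- numeric(n_tgt)
  for (j in seq_len(n_tgt)) {
    d2 <- colSums((st - target_coords[j, ])^2)
    k <- which.min(d2)
    idx[j] <- k
    dst[j] <- sqrt(d2[k])
  }
  list(index = idx, distance = dst)
}

#' Nearest-vertex correspondence between two meshes
#'
#' Matches each target vertex to the closest source vertex by chord
#' distance, the standard way of carrying values between surface templates
#' that share an embedding but not a mesh. Deterministic under ties
#' (lowest source index wins).
#'
#' @param mesh_src,mesh_tgt [spherical_mesh()] objects on the same hemisphere.
#' @return A [correspondence_table()] with one row per target vertex.
#' @export
nearest_source <- function(mesh_src, mesh_tgt) {
  if (mesh_src$hemisphere != mesh_tgt$hemisphere) {
    stop_invalid("meshes must be on the same hemisphere")
  }
  nn <- nearest_index(mesh_src$vertices, mesh_tgt$vertices)
  correspondence_table(nn$index, nn$distance,
                       source_id = mesh_src$resolution_id,
                       target_id = mesh_tgt$resolution_id)
}
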