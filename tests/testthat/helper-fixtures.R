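# Shared fixtures: meshes are memoized per session, and the brute-force
# oracles used by several test files live here. Oracles deliberately take
# the slow, literal route (exhaustive scans, direct definitions) and never
# call the code path they check.

.fixture_env <- new.env(parent = emptyenv())

ico <- function(s, hemisphere = "left") {
  key <- paste0("ico", s, "_", hemisphere)
  m <- .fixture_env[[key]]
  if (is.null(m)) {
    m <- build_icosphere(s, hemisphere)
    .fixture_env[[key]] <- m
  }
  m
}

# Exhaustive nearest-source scan: per target vertex, sqrt of squared
# coordinate differences against every source vertex, first minimum wins.
oracle_nearest <- function(src_vertices, tgt_vertices) {
  idx <- integer(nrow(tgt_vertices))
  dst <- numeric(nrow(tgt_vertices))
  for (j in seq_len(nrow(tgt_vertices))) {
    d <- sqrt(rowSums(sweep(src_vertices, 2, tgt_vertices[j, ])^2))
    idx[j] <- which.min(d)
    dst[j] <- d[idx[j]]
  }
  list(index = idx, distance = dst)
}

# Brute-force variogram: loop over all pairs, accumulate per bin.
oracle_variogram <- function(values, mask, coords, n_bins, max_quantile) {
  L <- length(values)
  pairs_d <- c()
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      pairs_d <- c(pairs_d, sqrt(sum((coords[i, ] - coords[j, ])^2)))
    }
  }
  dmax <- unname(quantile(pairs_d, max_quantile))
  breaks <- seq(0, dmax, length.out = n_bins + 1)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  k <- 0
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      k <- k + 1
      d <- pairs_d[k]
      if (d > dmax || d <= 0 || !mask[i] || !mask[j]) next
      b <- min(max(findInterval(d, breaks, rightmost.closed = TRUE), 1), n_bins)
      sums[b] <- sums[b] + (values[i] - values[j])^2
      counts[b] <- counts[b] + 1L
    }
  }
  list(gamma = ifelse(counts > 0, 0.5 * sums / counts, NA_real_), count = counts)
}

# Brute-force spin of one rotation: explicit distance scan per vertex.
oracle_spin <- function(values, vertices, R) {
  rotated <- vertices %*% R
  out <- numeric(nrow(vertices))
  for (i in seq_len(nrow(vertices))) {
    d <- sqrt(rowSums(sweep(rotated, 2, vertices[i, ])^2))
    out[i] <- values[which.min(d)]
  }
  out
}

# Brute-force project-rotate-aggregate for parcellated spins.
oracle_spin_parcellated <- function(values, labels, vertices, mask, R,
                                    strategy, ids) {
  L <- nrow(vertices)
  vert_values <- rep(NA_real_, L)
  vert_values[labels > 0] <- values[match(labels[labels > 0], ids)]
  vert_values[!mask] <- NA_real_
  if (strategy == "ignore") {
    keep <- which(mask)
    spun <- oracle_spin(vert_values[keep], vertices[keep, , drop = FALSE], R)
    lab <- labels[keep]
  } else {
    spun <- oracle_spin(vert_values, vertices, R)
    lab <- labels
  }
  out <- sapply(ids, function(id) {
    v <- spun[lab == id]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  if (strategy == "nearest" && anyNA(out)) {
    cent <- t(sapply(ids, function(id) colMeans(vertices[labels == id, , drop = FALSE])))
    pres <- which(!is.na(out)) # donors are the originally non-missing parcels
    for (m in which(is.na(out))) {
      d <- sqrt(rowSums(sweep(cent[pres, , drop = FALSE], 2, cent[m, ])^2))
      out[m] <- out[pres[which.min(d)]]
    }
  }
  unname(out)
}

identity_rotation <- function() {
  structure(list(R = diag(3), R_mirror = diag(3), seed = 0L),
            class = "rotation_sample")
}

# Edge-connectivity of a vertex subset (flood fill over mesh edges).
is_connected_subset <- function(mesh, subset_idx) {
  if (length(subset_idx) <= 1) return(TRUE)
  e <- spinmaps:::mesh_edges(mesh)
  inset <- e[, 1] %in% subset_idx & e[, 2] %in% subset_idx
  e <- e[inset, , drop = FALSE]
  seen <- subset_idx[1]
  repeat {
    nb <- unique(c(e[e[, 1] %in% seen, 2], e[e[, 2] %in% seen, 1]))
    new <- setdiff(nb, seen)
    if (length(new) == 0) break
    seen <- c(seen, new)
  }
  length(seen) == length(subset_idx)
}
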