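# Moran spectral randomization. Surrogates are built in the basis of
# Moran eigenvector maps (eigenvectors of the doubly centered spatial
# weight matrix): the map's coefficients in that basis are mixed by random
# orthogonal matrices within subspaces of (near-)equal eigenvalue, which
# preserves the variance exactly and the Moran's I of the map up to the
# grouping tolerance, while randomizing its topography.

#' Spatial weight matrices for a mesh
#'
#' `"edge_adjacency"` gives binary weights along triangulation edges;
#' `"knn_inverse_distance"` connects each vertex to its `k` nearest
#' neighbours (chord distance) with weight `1/d`, symmetrized by the union
#' of the directed k-NN graphs. Both are symmetric with zero diagonal.
#'
#' @param mesh a [spherical_mesh()].
#' @param method `"edge_adjacency"` or `"knn_inverse_distance"`.
#' @param k neighbour count for the k-NN method.
#' @return A dense symmetric `L x L` weight matrix.
#' @export
build_weights <- function(mesh, method = c("edge_adjacency", "knn_inverse_distance"),
                          k = 6L) {
  method <- match.arg(method)
  L <- n_vertices(mesh)
  w <- matrix(0, L, L)
  if (method == "edge_adjacency") {
    e <- mesh_edges(mesh)
    w[e] <- 1
    w[e[, c(2L, 1L)]] <- 1
  } else {
    if (k < 1L) stop_invalid("'k' must be >= 1")
    d <- cached_chords(mesh)
    for (i in seq_len(L)) {
      nb <- order(d[i, ])[2:(k + 1L)] # skip self at distance 0
      w[i, nb] <- 1 / d[i, nb]
    }
    w <- pmax(w, t(w))
  }
  diag(w) <- 0
  w
}

#' Moran's I
#'
#' Global spatial autocorrelation statistic
#' `I = (n / S0) * (x_c' W x_c) / (x_c' x_c)` over valid locations, with
#' `x_c` the centered values and `S0 = sum(W)`. Weight rows/columns of
#' masked locations are dropped. By default rows are standardized to sum
#' to 1 first (the convention used throughout the package's tests).
#'
#' @param map a [scalar_map()] (or plain numeric vector).
#' @param weights symmetric weight matrix over the map's locations.
#' @param row_standardize divide each row by its sum before computing.
#' @return Scalar Moran's I.
#' @export
moran_i <- function(map, weights, row_standardize = TRUE) {
  if (inherits(map, "scalar_map")) {
    x <- map$values[map$mask]
    w <- weights[map$mask, map$mask, drop = FALSE]
  } else {
    x <- as.numeric(map)
    w <- weights
    keep <- !is.na(x)
    x <- x[keep]
    w <- w[keep, keep, drop = FALSE]
  }
  if (row_standardize) {
    rs <- rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  n <- length(x)
  xc <- x - mean(x)
  (n / sum(w)) * as.numeric(xc %*% w %*% xc) / sum(xc^2)
}

# Connectivity of the positive-weight graph (BFS).
weights_connected <- function(w) {
  n <- nrow(w)
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0L) {
    v <- queue[1L]; queue <- queue[-1L]
    nb <- which(w[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

random_orthogonal <- function(n) {
  if (n == 1L) return(matrix(sample(c(-1, 1), 1L), 1L, 1L))
  g <- matrix(stats::rnorm(n * n), n, n)
  qr_g <- qr(g)
  qr.Q(qr_g) %*% diag(sign(diag(qr.R(qr_g))), n)
}

#' Moran spectral randomization nulls
#'
#' Decomposes the doubly centered symmetric weight matrix into Moran
#' eigenvector maps, expresses the (centered) map in that basis, applies a
#' random orthogonal rotation to the coefficients within each group of
#' near-equal eigenvalues, and reconstructs. Each surrogate keeps the
#' source map's mean and variance exactly and its Moran's I approximately.
#'
#' @param map a [scalar_map()].
#' @param weights symmetric zero-diagonal weight matrix over the map's
#'   locations, connected on the valid ones.
#' @param n_null number of surrogates.
#' @param seed integer seed.
#' @param eig_tol relative tolerance for grouping eigenvalues into
#'   degenerate subspaces.
#' @param identity_mix keep the coefficients unpermuted (test hook: every
#'   surrogate equals the source map).
#' @return A [null_ensemble()] with framework `"moran"`.
#' @export
moran_null <- function(map, weights, n_null, seed, eig_tol = 1e-8,
                       identity_mix = FALSE) {
  if (n_null < 1L) stop_invalid("'n_null' must be >= 1")
  mask <- map$mask
  w <- weights[mask, mask, drop = FALSE]
  if (max(abs(w - t(w))) > 1e-12) stop_invalid("'weights' must be symmetric")
  if (any(diag(w) != 0)) stop_invalid("'weights' must have a zero diagonal")
  if (!weights_connected(w)) {
    stop_invalid("weight graph is disconnected on the valid locations")
  }
  x <- map$values[mask]
  n <- length(x)

  key <- paste0("MEM_", content_digest(list(w)))
  basis <- .geom_cache[[key]]
  if (is.null(basis)) {
    h <- diag(n) - matrix(1 / n, n, n)
    eig <- eigen(h %*% ((w + t(w)) / 2) %*% h, symmetric = TRUE)
    # Drop the trivial direction spanned by the constant vector (H kernel).
    const <- abs(colSums(eig$vectors)) / sqrt(n)
    trivial <- which.max(const)
    vectors <- eig$vectors[, -trivial, drop = FALSE]
    lambdas <- eig$values[-trivial]
    basis <- list(vectors = vectors, lambdas = lambdas)
    .geom_cache[[key]] <- basis
  }
  vectors <- basis$vectors
  lambdas <- basis$lambdas

  # Group near-equal eigenvalues into degenerate subspaces.
  scale_ref <- max(abs(lambdas), 1e-30)
  groups <- cumsum(c(TRUE, diff(lambdas) < -eig_tol * scale_ref |
                             diff(lambdas) > eig_tol * scale_ref))
  coeffs <- as.numeric(crossprod(vectors, x - mean(x)))

  seeds <- derive_seeds(seed, n_null)
  L <- length(map$values)
  out <- matrix(NA_real_, n_null, L)
  sd_x <- stats::sd(x); mu_x <- mean(x)
  for (k in seq_len(n_null)) {
    ck <- if (identity_mix) {
      coeffs
    } else {
      with_seed(seeds[k], {
        ck <- coeffs
        for (g in unique(groups)) {
          idx <- which(groups == g)
          ck[idx] <- as.numeric(random_orthogonal(length(idx)) %*% coeffs[idx])
        }
        ck
      })
    }
    y <- as.numeric(vectors %*% ck)
    y <- (y - mean(y)) / stats::sd(y) * sd_x + mu_x
    row <- rep(NA_real_, L)
    row[mask] <- y
    out[k, ] <- row
  }
  null_ensemble(out, "moran", seed,
                params = list(n_null = n_null, eig_tol = eig_tol),
                space_key = space_digest(map$space))
}
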