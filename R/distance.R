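#' Pairwise distance matrix of a point cloud
#'
#' Computes the full symmetric `N x N` matrix of pairwise distances under the
#' L2 (Euclidean), L1 (Manhattan) or normalized-L1 metric. Normalized L1
#' divides the Manhattan distance by the feature dimensionality `D`, so that
#' distances between points in a fixed volume stay finite as `D` grows; the
#' expected normalized-L1 distance between two uniform points in the unit
#' hypercube is 1/3 in the large-`D` limit.
#'
#' @param points A [point_cloud()], or a plain numeric matrix of coordinates
#'   (rows = samples).
#' @param metric One of `"l2"`, `"l1"`, `"normalized-l1"`.
#' @return An object of class `dist_matrix`: list with `values` (numeric
#'   `N x N` matrix), `metric`, and `n`.
#' @examples
#' d <- dist_matrix(rbind(c(0, 0), c(3, 4)), "l2")
#' d$values[1, 2]  # 5
#' @export
dist_matrix <- function(points, metric = c("l2", "l1", "normalized-l1")) {
  metric <- match.arg(metric)
  x <- if (inherits(points, "point_cloud")) points$coordinates
       else as.matrix(points)
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("coordinates must be finite numeric values", call. = FALSE)
  }
  v <- switch(metric,
    "l2" = as.matrix(stats::dist(x, method = "euclidean")),
    "l1" = as.matrix(stats::dist(x, method = "manhattan")),
    "normalized-l1" = as.matrix(stats::dist(x, method = "manhattan")) / ncol(x)
  )
  dimnames(v) <- NULL
  new_dist_matrix(v, metric)
}

new_dist_matrix <- function(values, metric) {
  structure(list(values = values, metric = metric, n = nrow(values)),
            class = "dist_matrix")
}

#' Validate and wrap a precomputed dissimilarity matrix
#'
#' Accepts a square matrix of dissimilarities computed elsewhere (for
#' instance an optimal-transport distance between spike-train patterns) and
#' checks the invariants the transform relies on: symmetry within a small
#' relative tolerance (external tools can carry round-off asymmetry, which is
#' symmetrized away), a zero diagonal, non-negative finite entries.
#'
#' @param values Square numeric matrix.
#' @param metric Metric tag to record; defaults to `"precomputed"`.
#' @param tol Relative tolerance for the symmetry and zero-diagonal checks.
#' @return A `dist_matrix`.
#' @export
as_dist_matrix <- function(values, metric = "precomputed", tol = 1e-8) {
  if (inherits(values, "dist_matrix")) return(values)
  if (inherits(values, "dod_matrix")) {
    return(new_dist_matrix(values$values, values$source_metric))
  }
  if (inherits(values, "dist")) values <- as.matrix(values)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop(sprintf("matrix is %d x %d, not square", nrow(values), ncol(values)),
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite entry at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  scale <- max(abs(values), 1)
  asym <- abs(values - t(values))
  if (max(asym) > tol * scale) {
    bad <- which(asym == max(asym), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "matrix is not symmetric: entry [%d,%d] = %g but [%d,%d] = %g",
      bad[1L], bad[2L], values[bad[1L], bad[2L]],
      bad[2L], bad[1L], values[bad[2L], bad[1L]]), call. = FALSE)
  }
  if (max(abs(diag(values))) > tol * scale) {
    stop(sprintf("diagonal is not zero (max |diag| = %g)",
                 max(abs(diag(values)))), call. = FALSE)
  }
  if (min(values) < -tol * scale) {
    stop(sprintf("negative dissimilarity (min = %g)", min(values)),
         call. = FALSE)
  }
  v <- (values + t(values)) / 2
  v[v < 0] <- 0
  diag(v) <- 0
  dimnames(v) <- NULL
  new_dist_matrix(v, metric)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d x %d, metric = %s\n", x$n, x$n, x$metric))
  invisible(x)
}

#' K-nearest-neighbor sets of every point
#'
#' For each point, the indices of its `k` nearest other points by the given
#' dissimilarity, ordered by ascending distance. A point is never its own
#' neighbor. Ties are broken by ascending index, which makes the sets
#' deterministic and independent of any random seed.
#'
#' @param dmatrix A `dist_matrix` (or `dod_matrix`).
#' @param k Neighborhood size, `1 <= k <= N - 1`.
#' @return An object of class `neighbor_sets`: list with `indices` (integer
#'   `N x k` matrix, row `i` = the ordered neighbor list of point `i`) and
#'   `k`.
#' @export
nearest_neighbor_sets <- function(dmatrix, k) {
  d <- as_dist_matrix(dmatrix)
  n <- d$n
  k <- check_k(k, n)
  v <- d$values
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- v[i, ]
    row[i] <- Inf                       # self-exclusion
    ord <- order(row, seq_along(row))   # ties -> ascending index
    idx[i, ] <- ord[seq_len(k)]
  }
  structure(list(indices = idx, k = k), class = "neighbor_sets")
}

check_k <- function(k, n) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k != round(k)) {
    stop("'k' must be a single integer", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1L) stop("'k' must be at least 1", call. = FALSE)
  if (k > n - 1L) {
    stop(sprintf("'k' = %d but only %d other points exist (need k <= N - 1)",
                 k, n - 1L), call. = FALSE)
  }
  k
}

#' @export
print.neighbor_sets <- function(x, ...) {
  cat(sprintf("neighbor_sets: %d points, k = %d\n", nrow(x$indices), x$k))
  invisible(x)
}
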