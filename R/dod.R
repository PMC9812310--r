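#' Distance-of-distance (DoD) transformation
#'
#' Rewrites a dissimilarity matrix `D` into a new matrix `F` in which the
#' dissimilarity between points `i` and `j` is the average absolute
#' difference between the two points' distances to their nearest-neighbor
#' reference sets:
#'
#' \deqn{f_{i,j} = \frac{1}{2K}\Big(\sum_{n \in I} |d_{n,i} - d_{n,j}|
#'   + \sum_{m \in J} |d_{m,i} - d_{m,j}|\Big)}
#'
#' where `I` and `J` are the `K`-nearest-neighbor sets of `i` and `j`
#' (self excluded; the partner point is allowed to appear in the other
#' point's set, and a reference point lying in both sets contributes one
#' term to each sum).
#'
#' In a high-dimensional space, two scattered noise points have very similar
#' distances to any reference point even when they are far apart, so their
#' transformed dissimilarity collapses towards zero, while distances within
#' and between dense clusters are nearly preserved. If the input obeys the
#' triangle inequality, every transformed entry is bounded above by the
#' original entry.
#'
#' @param dmatrix A `dist_matrix` (or anything [as_dist_matrix()] accepts).
#' @param k Per-point neighborhood size `K`, `1 <= k <= N - 1`. Joint
#'   reference set size is `2K`.
#' @param labels Optional per-sample labels. When given, a warning is issued
#'   if `k` reaches the smallest declared cluster size: reference sets then
#'   spill out of the cluster and the transform degrades as `k` approaches
#'   `N`.
#' @return An object of class `dod_matrix`: list with `values` (the
#'   transformed `N x N` matrix, symmetric, zero diagonal), `k`, and
#'   `source_metric`.
#' @seealso [dod_transform_oracle()] for the literal reference
#'   implementation, [measure_shrinkage()] for pair-type summaries.
#' @examples
#' d <- dist_matrix(matrix(c(0, 1, 3), 3, 1), "l1")
#' dod_transform(d, k = 1)$values
#' @export
dod_transform <- function(dmatrix, k, labels = NULL) {
  d <- as_dist_matrix(dmatrix)
  n <- d$n
  k <- check_k(k, n)
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n) {
      stop(sprintf("'labels' has length %d but matrix has %d rows",
                   length(labels), n), call. = FALSE)
    }
    sizes <- table(labels[labels != NOISE_LABEL])
    if (length(sizes) && k >= min(sizes)) {
      warning(sprintf(
        "k = %d reaches the smallest cluster size (%d); neighborhoods spill out of clusters and the transform degrades as k approaches N",
        k, min(sizes)), call. = FALSE)
    }
  }
  v <- d$values
  nn <- nearest_neighbor_sets(d, k)$indices
  ## a[i, j] = sum over i's reference set I of |d_{n,i} - d_{n,j}|;
  ## symmetrizing adds the J sum. O(N^2 k) time, O(N^2) memory.
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ref <- v[nn[i, ], , drop = FALSE]          # k x n: d_{n, .}
    a[i, ] <- .colSums(abs(ref - v[cbind(nn[i, ], i)]), k, n)
  }
  f <- (a + t(a)) / (2 * k)
  diag(f) <- 0
  structure(list(values = f, k = k, source_metric = d$metric),
            class = "dod_matrix")
}

#' @export
print.dod_matrix <- function(x, ...) {
  cat(sprintf("dod_matrix: %d x %d, k = %d, source metric = %s\n",
              nrow(x$values), ncol(x$values), x$k, x$source_metric))
  invisible(x)
}

#' Naive reference implementation of the DoD transformation
#'
#' Computes exactly the same quantity as [dod_transform()] by literal nested
#' loops over the defining sums, term by term, with no vectorization or
#' shared intermediates. It exists purely as an independent oracle for
#' testing the optimized implementation and is quadratic-times-`k` slow;
#' do not use it on large matrices.
#'
#' @inheritParams dod_transform
#' @return A `dod_matrix`, entrywise equal to `dod_transform(dmatrix, k)` up
#'   to floating-point rounding.
#' @export
dod_transform_oracle <- function(dmatrix, k) {
  d <- as_dist_matrix(dmatrix)
  n <- d$n
  k <- check_k(k, n)
  v <- d$values
  nbr <- nearest_neighbor_sets(d, k)$indices
  f <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0
      for (idx in seq_len(k)) {         # sum over I, i's neighbors
        nn <- nbr[i, idx]
        s <- s + abs(v[nn, i] - v[nn, j])
      }
      for (idx in seq_len(k)) {         # sum over J, j's neighbors
        mm <- nbr[j, idx]
        s <- s + abs(v[mm, i] - v[mm, j])
      }
      f[i, j] <- s / (2 * k)
    }
  }
  structure(list(values = f, k = k, source_metric = d$metric),
            class = "dod_matrix")
}
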