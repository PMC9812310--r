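#' Two-dimensional embedding of a dissimilarity matrix
#'
#' Runs t-SNE (default) or UMAP on a precomputed dissimilarity matrix and
#' returns the 2-D coordinates. The embedding algorithms are established
#' implementations (\pkg{Rtsne}, \pkg{uwot}); this function only fixes the
#' precomputed-input plumbing and the seeding so that identical inputs and
#' seeds give identical coordinates.
#'
#' @param dissimilarity A `dist_matrix` or `dod_matrix`.
#' @param perplexity t-SNE perplexity (effective neighborhood size);
#'   must satisfy `1 < perplexity` and `3 * perplexity < N - 1`.
#' @param seed Integer seed for the stochastic initialization.
#' @param method `"tsne"` (default) or `"umap"` (pass-through; requires the
#'   \pkg{uwot} package).
#' @param ... Further arguments passed to [Rtsne::Rtsne()] or [uwot::umap()].
#' @return Numeric `N x 2` matrix of embedding coordinates.
#' @export
embed_2d <- function(dissimilarity, perplexity = 30, seed = NULL,
                     method = c("tsne", "umap"), ...) {
  method <- match.arg(method)
  v <- if (inherits(dissimilarity, "dod_matrix")) dissimilarity$values
       else as_dist_matrix(dissimilarity)$values
  n <- nrow(v)
  if (method == "tsne") {
    if (!is.numeric(perplexity) || length(perplexity) != 1L ||
        perplexity <= 1 || perplexity >= n) {
      stop(sprintf("'perplexity' must lie in (1, N); got %s with N = %d",
                   format(perplexity), n), call. = FALSE)
    }
    if (3 * perplexity > n - 1) {
      stop(sprintf(
        "'perplexity' = %g too large for N = %d (need 3 * perplexity < N - 1)",
        perplexity, n), call. = FALSE)
    }
    emb <- with_seed(seed,
      Rtsne::Rtsne(v, dims = 2, perplexity = perplexity, is_distance = TRUE,
                   pca = FALSE, check_duplicates = FALSE, num_threads = 1L,
                   ...)$Y)
  } else {
    if (!requireNamespace("uwot", quietly = TRUE)) {
      stop("method = 'umap' requires the 'uwot' package", call. = FALSE)
    }
    emb <- with_seed(seed,
      uwot::umap(stats::as.dist(v), n_threads = 1L, ...))
  }
  unname(as.matrix(emb))
}

#' K-means clustering of an embedding, scored against ground truth
#'
#' Clusters the 2-D embedding with K-means (seeded, multiple restarts, best
#' inertia kept) and scores the partition against the true labels with the
#' adjusted Rand index, treating all noise points as one class. The default
#' number of clusters is the number of true cluster labels plus one, so the
#' noise group can claim a cluster of its own.
#'
#' @param embedding Numeric `N x 2` (or `N x p`) coordinate matrix.
#' @param true_labels Per-sample labels; [NOISE_LABEL] marks the noise class.
#' @param n_clusters Number of K-means clusters; default: number of distinct
#'   cluster labels, plus one if noise is present.
#' @param seed Integer seed for the K-means restarts.
#' @param nstart Number of seeded restarts (best within-cluster sum of
#'   squares kept).
#' @return An object of class `clustering_eval`: list with `ari`,
#'   `inferred_labels`, `n_clusters`, `embedding`, `seed`.
#' @export
cluster_and_score <- function(embedding, true_labels, n_clusters = NULL,
                              seed = NULL, nstart = 10L) {
  embedding <- as.matrix(embedding)
  true_labels <- as.character(true_labels)
  if (nrow(embedding) != length(true_labels)) {
    stop("embedding and labels disagree in length", call. = FALSE)
  }
  if (is.null(n_clusters)) {
    n_clusters <- length(setdiff(unique(true_labels), NOISE_LABEL)) +
      as.integer(NOISE_LABEL %in% true_labels)
  }
  if (n_clusters < 2) stop("'n_clusters' must be at least 2", call. = FALSE)
  if (all(apply(embedding, 2L, function(col) length(unique(col)) == 1L))) {
    warning("degenerate embedding (all points identical); ARI set to 0",
            call. = FALSE)
    return(structure(list(ari = 0, inferred_labels = rep(1L, nrow(embedding)),
                          n_clusters = n_clusters, embedding = embedding,
                          seed = seed),
                     class = "clustering_eval"))
  }
  km <- with_seed(seed,
    stats::kmeans(embedding, centers = n_clusters, nstart = nstart,
                  iter.max = 100L))
  structure(list(ari = mclust::adjustedRandIndex(km$cluster, true_labels),
                 inferred_labels = km$cluster, n_clusters = n_clusters,
                 embedding = embedding, seed = seed),
            class = "clustering_eval")
}

#' @export
print.clustering_eval <- function(x, ...) {
  cat(sprintf("clustering_eval: %d points, %d clusters, ARI = %.3f\n",
              nrow(x$embedding), x$n_clusters, x$ari))
  invisible(x)
}

#' Cross-validated KNN classification score on a dissimilarity matrix
#'
#' A K-nearest-neighbor classifier operating directly on a precomputed
#' dissimilarity matrix: a test point is assigned the majority label of its
#' `k` nearest training points. The neighbor count is selected from `k_grid`
#' by stratified cross-validated accuracy, and the accuracy at the selected
#' `k` is reported. Used to quantify, on labelled noise-free data, whether
#' the transform preserves (or sharpens) class structure.
#'
#' @param dissimilarity A `dist_matrix` or `dod_matrix`.
#' @param labels Per-sample class labels (at least 2 classes; every class at
#'   least `n_folds` members).
#' @param k_grid Candidate neighbor counts.
#' @param n_folds Number of stratified folds (default 5).
#' @param seed Integer seed for the fold assignment.
#' @return List with `score` (cross-validated accuracy at the selected `k`),
#'   `best_k`, and `accuracy_by_k` (named vector over `k_grid`).
#' @export
knn_cv_score <- function(dissimilarity, labels, k_grid = c(1, 3, 5, 7, 9),
                         n_folds = 5, seed = NULL) {
  v <- if (inherits(dissimilarity, "dod_matrix")) dissimilarity$values
       else as_dist_matrix(dissimilarity)$values
  labels <- as.character(labels)
  n <- nrow(v)
  if (length(labels) != n) {
    stop("labels and matrix disagree in size", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("need at least 2 classes", call. = FALSE)
  }
  if (n_folds < 2L) stop("'n_folds' must be at least 2", call. = FALSE)
  sizes <- table(labels)
  if (min(sizes) < n_folds) {
    stop(sprintf("class '%s' has %d members, fewer than n_folds = %d",
                 names(sizes)[which.min(sizes)], min(sizes), n_folds),
         call. = FALSE)
  }
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1L)) stop("'k_grid' entries must be >= 1", call. = FALSE)

  ## stratified fold assignment: shuffle within class, deal round-robin
  fold <- integer(n)
  with_seed(seed, {
    for (cls in names(sizes)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })

  votes <- function(dist_to_train, train_labels, k) {
    ord <- order(dist_to_train, seq_along(dist_to_train))[seq_len(k)]
    tab <- sort(table(train_labels[ord]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) return(top)
    ## tie-break: smallest summed distance among the tied classes
    sums <- vapply(top, function(cls) {
      sum(dist_to_train[ord][train_labels[ord] == cls])
    }, numeric(1))
    top[order(sums, top)][1L]
  }

  acc <- matrix(NA_real_, n_folds, length(k_grid),
                dimnames = list(NULL, as.character(k_grid)))
  for (f in seq_len(n_folds)) {
    test <- which(fold == f)
    train <- which(fold != f)
    kk_max <- min(max(k_grid), length(train))
    for (ki in seq_along(k_grid)) {
      k <- min(k_grid[ki], length(train))
      pred <- vapply(test, function(i) votes(v[i, train], labels[train], k),
                     character(1))
      acc[f, ki] <- mean(pred == labels[test])
    }
  }
  mean_acc <- colMeans(acc)
  best <- which.max(mean_acc)          # ties -> smallest k
  list(score = unname(mean_acc[best]),
       best_k = k_grid[best],
       accuracy_by_k = mean_acc)
}

#' Unsupervised noise detection by neighborhood-overlap rate
#'
#' For every point, measures how much its `k`-nearest-neighbor set changes
#' under the transform: `overlap_rate = |NN_k(original) intersect
#' NN_k(transformed)| / k`. Cluster points keep their neighborhoods (rates
#' near 1); scattering noise points acquire entirely new neighbors (low
#' rates) because the transform rewrites their local geometry. Points with
#' `overlap_rate < threshold` are flagged as noise; the conventional
#' threshold is 0.65.
#'
#' @param original A `dist_matrix`.
#' @param transformed The matching `dod_matrix`.
#' @param k Neighborhood size used for the overlap (need not equal the
#'   transform's `k`).
#' @param threshold Flagging threshold in `(0, 1]`; a point is noise iff its
#'   rate is strictly below it. `threshold = 0` flags nothing.
#' @return An object of class `noise_call`: list with `overlap_rate`
#'   (numeric per point), `threshold`, `is_noise` (logical per point), `k`.
#' @export
detect_noise <- function(original, transformed, k, threshold = 0.65) {
  d <- as_dist_matrix(original)
  if (!inherits(transformed, "dod_matrix") &&
      !inherits(transformed, "dist_matrix")) {
    transformed <- as_dist_matrix(transformed)
  }
  tv <- if (inherits(transformed, "dod_matrix")) transformed$values
        else transformed$values
  if (!all(dim(tv) == dim(d$values))) {
    stop("original and transformed matrices have different sizes",
         call. = FALSE)
  }
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("'threshold' must lie in [0, 1]", call. = FALSE)
  }
  k <- check_k(k, d$n)
  nn_before <- nearest_neighbor_sets(d, k)$indices
  nn_after <- nearest_neighbor_sets(new_dist_matrix(tv, "transformed"),
                                    k)$indices
  rate <- vapply(seq_len(d$n), function(i) {
    length(intersect(nn_before[i, ], nn_after[i, ])) / k
  }, numeric(1))
  structure(list(overlap_rate = rate, threshold = threshold,
                 is_noise = rate < threshold, k = k),
            class = "noise_call")
}

#' @export
print.noise_call <- function(x, ...) {
  cat(sprintf(
    "noise_call: %d points, k = %d, threshold = %.2f -> %d flagged as noise\n",
    length(x$overlap_rate), x$k, x$threshold, sum(x$is_noise)))
  invisible(x)
}

#' Precision, recall and F1 of a noise call against ground truth
#'
#' @param call A `noise_call`.
#' @param true_labels Per-sample labels with [NOISE_LABEL] marking true
#'   noise.
#' @return Named numeric vector `precision`, `recall`, `f1`, `n_flagged`.
#' @export
score_noise_call <- function(call, true_labels) {
  truth <- as.character(true_labels) == NOISE_LABEL
  flag <- call$is_noise
  tp <- sum(flag & truth)
  prec <- if (sum(flag) > 0) tp / sum(flag) else 0
  rec <- if (sum(truth) > 0) tp / sum(truth) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1, n_flagged = sum(flag))
}
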