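## Benchmark experiment drivers: each returns a tidy data.frame and is
## deterministic given its seed vector. replicate_figure() wraps these with
## file output for the command-line `replicate` subcommand.

#' Clustering-improvement experiment (embedding + K-means + ARI)
#'
#' For each seed: generate Gaussian clusters plus uniform noise, embed the
#' original and the DoD-transformed dissimilarity matrices in 2-D, cluster
#' both embeddings with K-means and score each partition against ground
#' truth (noise as one class) with the adjusted Rand index.
#'
#' @param seeds Integer vector of master seeds (one row per seed).
#' @param m_clusters,n_per_cluster,n_noise,n_features,sd Scenario parameters
#'   (see [sim_noisy_gaussians()]).
#' @param metric Distance metric for the original matrix.
#' @param k DoD neighborhood size.
#' @param perplexity t-SNE perplexity.
#' @param n_clusters K-means cluster count; default number of clusters + 1.
#' @param method Embedding method passed to [embed_2d()].
#' @return `data.frame` with one row per seed: scenario parameters,
#'   `ari_before`, `ari_after`.
#' @export
run_ari_experiment <- function(seeds, m_clusters = 5, n_per_cluster = 20,
                               n_noise = 500, n_features = 20, sd = 0.1,
                               metric = "l2", k = 10, perplexity = 30,
                               n_clusters = NULL, method = "tsne") {
  rows <- lapply(seeds, function(s) {
    pc <- sim_noisy_gaussians(m_clusters, n_per_cluster, n_noise, n_features,
                              sd = sd, seed = s)
    d <- dist_matrix(pc, metric)
    f <- dod_transform(d, k)
    ari <- vapply(list(d, f), function(mat) {
      emb <- embed_2d(mat, perplexity = perplexity, seed = sub_seed(s, 3L),
                      method = method)
      cluster_and_score(emb, pc$labels, n_clusters = n_clusters,
                        seed = sub_seed(s, 4L))$ari
    }, numeric(1))
    data.frame(seed = s, D = n_features, n_noise = n_noise, k = k,
               perplexity = perplexity, ari_before = ari[1L],
               ari_after = ari[2L])
  })
  do.call(rbind, rows)
}

#' Pair-type shrinkage experiment over a dimensionality or sample-size grid
#'
#' For each seed and each (D, n_noise) grid cell: generate the scenario,
#' transform, and summarize the per-pair-type shrinkage with
#' [measure_shrinkage()]. With `generator = "theory"` the clusters are
#' coincident points (infinite density), in which case cluster-cluster
#' distances are preserved exactly for `k < n_per_cluster`.
#'
#' @param seeds Integer vector of master seeds.
#' @param dims Integer vector of dimensionalities to sweep.
#' @param n_noise_values Integer vector of noise counts to sweep (crossed
#'   with `dims`).
#' @param m_clusters,n_per_cluster,sd Scenario parameters.
#' @param metric Distance metric.
#' @param k DoD neighborhood size.
#' @param generator `"gaussian"` (sd-`sd` clusters) or `"theory"`
#'   (coincident clusters).
#' @return Tidy `data.frame`: seed, D, n_noise, pair_type, n_pairs,
#'   mean_original, mean_transformed, delta, fraction.
#' @export
run_shrinkage_experiment <- function(seeds, dims = c(5, 10, 20, 50),
                                     n_noise_values = 200, m_clusters = 5,
                                     n_per_cluster = 20, sd = 0.1,
                                     metric = "l2", k = 10,
                                     generator = c("gaussian", "theory")) {
  generator <- match.arg(generator)
  grid <- expand.grid(D = dims, n_noise = n_noise_values, seed = seeds)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    D <- grid$D[g]; n_noise <- grid$n_noise[g]; s <- grid$seed[g]
    pc <- if (generator == "theory") {
      sim_theory_scenario(m_clusters, n_per_cluster, n_noise, D, seed = s)
    } else {
      sim_noisy_gaussians(m_clusters, n_per_cluster, n_noise, D, sd = sd,
                          seed = s)
    }
    d <- dist_matrix(pc, metric)
    f <- dod_transform(d, k)
    cbind(data.frame(seed = s, D = D, n_noise = n_noise),
          measure_shrinkage(d, f, pc$labels))
  })
  do.call(rbind, rows)
}

#' Noise-detection experiment (overlap-rate flags vs ground truth)
#'
#' For each seed: generate the scenario, flag noise points whose
#' neighborhood-overlap rate falls below the threshold, and score the flags
#' against ground truth, alongside a size-matched random baseline flag drawn
#' from the same seed.
#'
#' @inheritParams run_ari_experiment
#' @param threshold Overlap-rate threshold (default 0.65).
#' @param overlap_k Neighborhood size for the overlap rate; defaults to the
#'   cluster size `n_per_cluster`. Below the cluster size the overlap mostly
#'   measures harmless intra-cluster rank reshuffling; at the cluster-size
#'   scale it measures genuine neighborhood-identity change, which is what
#'   separates noise from cluster points.
#' @return `data.frame` with one row per seed: precision, recall, f1,
#'   n_flagged, and `f1_random` for the baseline.
#' @export
run_noise_detection_experiment <- function(seeds, m_clusters = 5,
                                           n_per_cluster = 20, n_noise = 200,
                                           n_features = 50, sd = 0.1,
                                           metric = "l2", k = 10,
                                           threshold = 0.65,
                                           overlap_k = n_per_cluster) {
  rows <- lapply(seeds, function(s) {
    pc <- sim_noisy_gaussians(m_clusters, n_per_cluster, n_noise, n_features,
                              sd = sd, seed = s)
    d <- dist_matrix(pc, metric)
    f <- dod_transform(d, k)
    call <- detect_noise(d, f, k = overlap_k, threshold = threshold)
    sc <- score_noise_call(call, pc$labels)
    ## random flag of equal size, same seed stream
    rand_flag <- with_seed(sub_seed(s, 9L), {
      flag <- rep(FALSE, pc$n_samples)
      flag[sample(pc$n_samples, sum(call$is_noise))] <- TRUE
      flag
    })
    rand_call <- structure(list(overlap_rate = NULL, threshold = threshold,
                                is_noise = rand_flag, k = overlap_k),
                           class = "noise_call")
    data.frame(seed = s, D = n_features, n_noise = n_noise, k = k,
               overlap_k = overlap_k,
               threshold = threshold, precision = sc[["precision"]],
               recall = sc[["recall"]], f1 = sc[["f1"]],
               n_flagged = sc[["n_flagged"]],
               f1_random = score_noise_call(rand_call, pc$labels)[["f1"]])
  })
  do.call(rbind, rows)
}

#' KNN-classification experiment on noise-free clusters
#'
#' For each seed: generate labelled Gaussian clusters (no noise), compute
#' the cross-validated KNN accuracy on the original and on the transformed
#' dissimilarity matrix. Quantifies that the transform does not destroy —
#' and on high-dimensional data typically sharpens — class structure.
#'
#' @inheritParams run_ari_experiment
#' @param k_grid Candidate KNN neighbor counts.
#' @param n_folds Cross-validation folds.
#' @return `data.frame` with one row per seed: `knn_before`, `knn_after`,
#'   selected neighbor counts.
#' @export
run_knn_experiment <- function(seeds, m_clusters = 5, n_per_cluster = 20,
                               n_features = 50, sd = 0.1, metric = "l2",
                               k = 10, k_grid = c(1, 3, 5, 7, 9),
                               n_folds = 5) {
  rows <- lapply(seeds, function(s) {
    pc <- sim_gaussian_clusters(m_clusters, n_per_cluster, n_features,
                                sd = sd, seed = sub_seed(s, 1L))
    d <- dist_matrix(pc, metric)
    f <- dod_transform(d, k)
    before <- knn_cv_score(d, pc$labels, k_grid = k_grid, n_folds = n_folds,
                           seed = sub_seed(s, 5L))
    after <- knn_cv_score(f, pc$labels, k_grid = k_grid, n_folds = n_folds,
                          seed = sub_seed(s, 5L))
    data.frame(seed = s, D = n_features, k = k, knn_before = before$score,
               knn_after = after$score, best_k_before = before$best_k,
               best_k_after = after$best_k)
  })
  do.call(rbind, rows)
}

## preset parameter sets for the replicate subcommand
figure_defaults <- function(id) {
  switch(id,
    fig1 = list(kind = "embed", m_clusters = 5, n_per_cluster = 20,
                n_noise = 200, n_features = 50, sd = 0.1, k = 10,
                metric = "l2", perplexity = 30),
    fig2 = list(kind = "embed_grid", m_clusters = 5, n_per_cluster = 20,
                sd = 0.1, k = 5, metric = "l2", perplexity = 30,
                grid = data.frame(n_features = c(5, 20, 20, 50),
                                  n_noise = c(200, 200, 2000, 2000))),
    fig3 = list(kind = "shrinkage", m_clusters = 5, n_per_cluster = 20,
                k = 10, metric = "l2", dims = c(5, 10, 20, 50),
                n_noise = 200, dims_fixed = 20,
                n_noise_values = c(256, 512, 1024, 2048, 4096)),
    fig4 = list(kind = "ari", m_clusters = 5, n_per_cluster = 20,
                n_noise = 500, n_features = 20, sd = 0.1, k = 10,
                metric = "l2", perplexity = 30),
    s1 = list(kind = "k_sweep", m_clusters = 5, n_per_cluster = 20,
              n_noise = 200, n_features = 50, sd = 0.1, metric = "l2",
              perplexity = 30, k_values = c(5, 20, 50, 100)),
    s2 = list(kind = "detect", m_clusters = 5, n_per_cluster = 20,
              n_noise = 200, n_features = 50, sd = 0.1, k = 10,
              metric = "l2", threshold = 0.65),
    s4 = list(kind = "embed", m_clusters = 50, n_per_cluster = 20,
              n_noise = 500, n_features = 50, sd = 0.1, k = 5,
              metric = "l2", perplexity = 30),
    s5 = list(kind = "perplexity_sweep", m_clusters = 50, n_per_cluster = 20,
              n_noise = 1000, n_features = 50, sd = 0.1, k = 5,
              metric = "l2", perplexity_values = c(5, 50, 100, 500)),
    s6 = list(kind = "noise_free", m_clusters = 5, n_per_cluster = 20,
              n_noise = 0, n_features = 50, metric = "l2", perplexity = 30,
              sd = c(0.5, 0.2, 0.2, 0.2, 0.2), k_values = c(5, 10, 20, 30)),
    stop(sprintf("unknown figure id '%s'", id), call. = FALSE)
  )
}

#' Replicate a packaged benchmark scenario end to end
#'
#' Runs one of the packaged benchmark scenarios with its preset
#' default parameters (overridable), writes tidy result tables (and, for
#' embedding scenarios, the 2-D coordinates) as tab-separated text into
#' `output_dir`, plus simple PDF scatter plots when `plot = TRUE`.
#' Deterministic given `seeds`.
#'
#' @param id One of `"fig1" "fig2" "fig3" "fig4" "s1" "s2" "s4" "s5" "s6"`.
#' @param output_dir Directory to write into (created if needed).
#' @param seeds Integer vector of master seeds; scenarios that need a single
#'   seed use the first.
#' @param overrides Named list of parameter overrides (matched against the
#'   scenario's defaults).
#' @param plot Also write PDF scatter plots of the embeddings.
#' @return Named list of the result tables, invisibly; files are the primary
#'   output.
#' @export
replicate_figure <- function(id, output_dir, seeds = 1:10,
                             overrides = list(), plot = TRUE) {
  p <- figure_defaults(id)
  unknown <- setdiff(names(overrides), c(names(p), "perplexity"))
  if (length(unknown)) {
    stop(sprintf("unknown override(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  p[names(overrides)] <- overrides
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  s1 <- seeds[1L]

  embed_pair <- function(pc, k, perplexity, seed, tag) {
    d <- dist_matrix(pc, p$metric)
    f <- dod_transform(d, k)
    eb <- embed_2d(d, perplexity = perplexity, seed = sub_seed(seed, 3L))
    ea <- embed_2d(f, perplexity = perplexity, seed = sub_seed(seed, 3L))
    tab <- data.frame(sample = seq_len(pc$n_samples), label = pc$labels,
                      x_before = eb[, 1L], y_before = eb[, 2L],
                      x_after = ea[, 1L], y_after = ea[, 2L])
    utils::write.table(tab, file.path(output_dir,
                                      sprintf("%s_embedding.tsv", tag)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (plot) plot_embedding_pair(tab, file.path(output_dir,
                                                 sprintf("%s.pdf", tag)))
    tab
  }

  if (p$kind == "embed") {
    pc <- sim_noisy_gaussians(p$m_clusters, p$n_per_cluster, p$n_noise,
                              p$n_features, sd = p$sd, seed = s1)
    log_stage("replicate", id = id, N = pc$n_samples, D = pc$n_features)
    out$embedding <- embed_pair(pc, p$k, p$perplexity, s1, id)
  } else if (p$kind == "embed_grid") {
    out$embedding <- lapply(seq_len(nrow(p$grid)), function(i) {
      pc <- sim_noisy_gaussians(p$m_clusters, p$n_per_cluster,
                                p$grid$n_noise[i], p$grid$n_features[i],
                                sd = p$sd, seed = s1)
      embed_pair(pc, p$k, p$perplexity, s1,
                 sprintf("%s_D%d_n%d", id, p$grid$n_features[i],
                         p$grid$n_noise[i]))
    })
  } else if (p$kind == "shrinkage") {
    by_d <- run_shrinkage_experiment(seeds, dims = p$dims,
                                     n_noise_values = p$n_noise,
                                     m_clusters = p$m_clusters,
                                     n_per_cluster = p$n_per_cluster,
                                     metric = p$metric, k = p$k,
                                     generator = "theory")
    by_n <- run_shrinkage_experiment(seeds, dims = p$dims_fixed,
                                     n_noise_values = p$n_noise_values,
                                     m_clusters = p$m_clusters,
                                     n_per_cluster = p$n_per_cluster,
                                     metric = p$metric, k = p$k,
                                     generator = "theory")
    utils::write.table(by_d, file.path(output_dir, "fig3_by_dimension.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(by_n, file.path(output_dir, "fig3_by_n_noise.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out <- list(by_dimension = by_d, by_n_noise = by_n)
  } else if (p$kind == "ari") {
    tab <- run_ari_experiment(seeds, m_clusters = p$m_clusters,
                              n_per_cluster = p$n_per_cluster,
                              n_noise = p$n_noise, n_features = p$n_features,
                              sd = p$sd, metric = p$metric, k = p$k,
                              perplexity = p$perplexity)
    utils::write.table(tab, file.path(output_dir, "fig4_ari.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out$ari <- tab
  } else if (p$kind == "k_sweep") {
    pc <- sim_noisy_gaussians(p$m_clusters, p$n_per_cluster, p$n_noise,
                              p$n_features, sd = p$sd, seed = s1)
    out$embedding <- lapply(p$k_values, function(k) {
      embed_pair(pc, k, p$perplexity, s1, sprintf("%s_k%d", id, k))
    })
  } else if (p$kind == "detect") {
    tab <- run_noise_detection_experiment(seeds, m_clusters = p$m_clusters,
                                          n_per_cluster = p$n_per_cluster,
                                          n_noise = p$n_noise,
                                          n_features = p$n_features,
                                          sd = p$sd, k = p$k,
                                          threshold = p$threshold)
    utils::write.table(tab, file.path(output_dir, "s2_noise_detection.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    ## per-point overlap rates of the first seed, for the histogram
    pc <- sim_noisy_gaussians(p$m_clusters, p$n_per_cluster, p$n_noise,
                              p$n_features, sd = p$sd, seed = s1)
    d <- dist_matrix(pc, p$metric)
    call <- detect_noise(d, dod_transform(d, p$k), k = p$n_per_cluster,
                         threshold = p$threshold)
    rates <- data.frame(sample = seq_len(pc$n_samples), label = pc$labels,
                        overlap_rate = call$overlap_rate,
                        is_noise = call$is_noise)
    utils::write.table(rates, file.path(output_dir, "s2_overlap_rates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out <- list(scores = tab, rates = rates)
  } else if (p$kind == "perplexity_sweep") {
    pc <- sim_noisy_gaussians(p$m_clusters, p$n_per_cluster, p$n_noise,
                              p$n_features, sd = p$sd, seed = s1)
    valid <- p$perplexity_values[3 * p$perplexity_values < pc$n_samples - 1]
    out$embedding <- lapply(valid, function(px) {
      embed_pair(pc, p$k, px, s1, sprintf("%s_perp%d", id, px))
    })
  } else if (p$kind == "noise_free") {
    pc <- sim_gaussian_clusters(p$m_clusters, p$n_per_cluster, p$n_features,
                                sd = p$sd, seed = s1)
    d <- dist_matrix(pc, p$metric)
    rows <- lapply(p$k_values, function(k) {
      f <- dod_transform(d, k)
      ari <- vapply(list(d, f), function(mat) {
        emb <- embed_2d(mat, perplexity = p$perplexity,
                        seed = sub_seed(s1, 3L))
        cluster_and_score(emb, pc$labels, seed = sub_seed(s1, 4L))$ari
      }, numeric(1))
      data.frame(k = k, ari_before = ari[1L], ari_after = ari[2L])
    })
    tab <- do.call(rbind, rows)
    utils::write.table(tab, file.path(output_dir, "s6_noise_free_ari.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    out$ari <- tab
  }
  invisible(out)
}

## side-by-side scatter of before/after embeddings; noise grey, clusters
## colored. Courtesy output only — analyses read the tables.
plot_embedding_pair <- function(tab, path) {
  grDevices::pdf(path, width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  labs <- unique(tab$label)
  cl <- setdiff(labs, NOISE_LABEL)
  pal <- grDevices::hcl.colors(max(length(cl), 2L), "Dark 3")
  col <- ifelse(tab$label == NOISE_LABEL, "grey60",
                pal[match(tab$label, cl)])
  graphics::par(mfrow = c(1, 2), mar = c(2, 2, 2, 1))
  graphics::plot(tab$x_before, tab$y_before, col = col, pch = 16, cex = 0.5,
                 main = "original", xlab = "", ylab = "")
  graphics::plot(tab$x_after, tab$y_after, col = col, pch = 16, cex = 0.5,
                 main = "DoD-transformed", xlab = "", ylab = "")
  invisible(path)
}
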