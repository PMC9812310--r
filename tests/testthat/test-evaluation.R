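test_that("embedding is deterministic given matrix and seed", {
  d <- random_metric_matrix(60, d = 5, seed = 1)
  e1 <- embed_2d(d, perplexity = 10, seed = 99)
  e2 <- embed_2d(d, perplexity = 10, seed = 99)
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(60L, 2L))
  e3 <- embed_2d(d, perplexity = 10, seed = 100)
  expect_false(identical(e1, e3))

  expect_error(embed_2d(d, perplexity = 1), "perplexity")
  expect_error(embed_2d(d, perplexity = 30, seed = 1), "perplexity")
})

test_that("clustering score behaves at its limits", {
  ## two well-separated blobs in the plane: kmeans recovers them -> ARI 1
  emb <- rbind(matrix(rnorm(40, 0, 0.05), 20, 2),
               matrix(rnorm(40, 5, 0.05), 20, 2))
  labels <- rep(c("1", "2"), each = 20)
  ev <- cluster_and_score(emb, labels, n_clusters = 2, seed = 1)
  expect_equal(ev$ari, 1)

  ## random labels score near zero by chance correction
  aris <- vapply(1:20, function(s) {
    shuffled <- dodist:::with_seed(s, sample(labels))
    cluster_and_score(emb, shuffled, n_clusters = 2, seed = 1)$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.1)

  ## degenerate embedding: warn, ARI 0
  expect_warning(dg <- cluster_and_score(matrix(1, 10, 2), rep(c("1", "2"), 5),
                                         n_clusters = 2), "degenerate")
  expect_equal(dg$ari, 0)

  ## default cluster count = true clusters + 1 when noise present
  labn <- c(rep("1", 5), rep("2", 5), rep(NOISE_LABEL, 5))
  ev2 <- cluster_and_score(matrix(rnorm(30), 15, 2), labn, seed = 1)
  expect_equal(ev2$n_clusters, 3L)
  expect_error(cluster_and_score(emb, labels[-1]), "length")
})

test_that("knn score is perfect on separable classes and near chance on shuffled labels", {
  pc <- sim_gaussian_clusters(3, 15, 10, sd = 1e-4, seed = 2)
  d <- dist_matrix(pc, "l2")
  res <- knn_cv_score(d, pc$labels, k_grid = c(1, 3, 5), seed = 1)
  expect_equal(res$score, 1)
  expect_true(res$best_k %in% c(1L, 3L, 5L))

  shuffled <- dodist:::with_seed(3, sample(pc$labels))
  res2 <- knn_cv_score(d, shuffled, k_grid = c(1, 3, 5), seed = 1)
  expect_lt(res2$score, 0.6)           # chance is 1/3

  expect_error(knn_cv_score(d, rep("a", 45)), "2 classes")
  expect_error(knn_cv_score(d, c(rep("a", 2), rep("b", 43))), "fewer than")
  expect_error(knn_cv_score(d, pc$labels, n_folds = 1), "at least 2")
})

test_that("knn fold assignment is seeded and stratified", {
  pc <- sim_gaussian_clusters(2, 25, 5, sd = 0.3, seed = 4)
  d <- dist_matrix(pc, "l2")
  a <- knn_cv_score(d, pc$labels, seed = 11)
  b <- knn_cv_score(d, pc$labels, seed = 11)
  expect_identical(a, b)
})

test_that("noise detector boundary behavior matches its contract", {
  pc <- sim_noisy_gaussians(3, 10, 30, 20, seed = 5)
  d <- dist_matrix(pc, "l2")
  f <- dod_transform(d, 5)

  ## identical matrices: all overlap rates 1, nothing flagged
  same <- detect_noise(d, d, k = 5)
  expect_true(all(same$overlap_rate == 1))
  expect_false(any(same$is_noise))

  ## threshold 0 flags nothing; threshold 1 flags every changed neighborhood
  none <- detect_noise(d, f, k = 5, threshold = 0)
  expect_false(any(none$is_noise))
  all_changed <- detect_noise(d, f, k = 5, threshold = 1)
  expect_equal(all_changed$is_noise, all_changed$overlap_rate < 1)

  ## is_noise <-> overlap_rate < threshold, rates in [0, 1]
  call <- detect_noise(d, f, k = 10, threshold = 0.65)
  expect_equal(call$is_noise, call$overlap_rate < 0.65)
  expect_true(all(call$overlap_rate >= 0 & call$overlap_rate <= 1))

  expect_error(detect_noise(d, f, k = 5, threshold = 2), "threshold")
  small <- as_dist_matrix(d$values[1:10, 1:10])
  expect_error(detect_noise(d, dod_transform(small, 2), k = 5),
               "different sizes")
})

test_that("overlap-rate flags recover planted noise far better than chance", {
  tab <- run_noise_detection_experiment(seeds = 1:3, n_noise = 100,
                                        n_features = 50)
  expect_true(all(tab$f1 > 0.9))
  expect_true(all(tab$f1 > tab$f1_random))
})

test_that("clustering of embeddings stays high without noise and across k", {
  ## noise-free control with one 2.5x-broader (lower-density) cluster; sds
  ## scaled so every cluster stays narrower than the typical separation of
  ## unit-hypercube centers, otherwise the scenario is unclusterable even
  ## before the transform
  pc <- sim_gaussian_clusters(5, 20, 50, sd = c(0.25, 0.1, 0.1, 0.1, 0.1),
                              seed = 8)
  d <- dist_matrix(pc, "l2")
  for (k in c(5, 10)) {
    f <- dod_transform(d, k)
    ari <- vapply(list(d, f), function(mat) {
      emb <- embed_2d(mat, perplexity = 15, seed = 21)
      cluster_and_score(emb, pc$labels, seed = 21)$ari
    }, numeric(1))
    expect_gt(ari[1], 0.85)
    expect_gt(ari[2], 0.85)
    expect_lt(abs(ari[2] - ari[1]), 0.15)
  }
})
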