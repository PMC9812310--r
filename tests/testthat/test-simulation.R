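test_that("gaussian cluster generator honors counts, labels and determinism", {
  pc <- sim_gaussian_clusters(5, 20, 50, sd = 0.1, seed = 7)
  expect_equal(pc$n_samples, 100L)
  expect_equal(pc$n_features, 50L)
  expect_equal(table(pc$labels), table(rep(as.character(1:5), each = 20)))

  ## same seed -> identical coordinates; different seed -> different
  pc2 <- sim_gaussian_clusters(5, 20, 50, sd = 0.1, seed = 7)
  expect_identical(pc$coordinates, pc2$coordinates)
  pc3 <- sim_gaussian_clusters(5, 20, 50, sd = 0.1, seed = 8)
  expect_false(identical(pc$coordinates, pc3$coordinates))

  ## tiny sd: points of a cluster nearly coincide
  tight <- sim_gaussian_clusters(2, 10, 5, sd = 1e-9, seed = 1)
  d <- dist_matrix(tight, "l2")$values
  expect_lt(max(d[1:10, 1:10]), 1e-7)

  ## per-cluster sd vector
  mixed <- sim_gaussian_clusters(2, 200, 10, sd = c(0.5, 0.05), seed = 2)
  s1 <- mean(apply(mixed$coordinates[1:200, ], 2, sd))
  s2 <- mean(apply(mixed$coordinates[201:400, ], 2, sd))
  expect_gt(s1 / s2, 5)

  expect_error(sim_gaussian_clusters(0, 5, 5), "positive integer")
  expect_error(sim_gaussian_clusters(2, 5, 5, sd = 0), "positive")
  expect_error(sim_gaussian_clusters(2, 5, 5, sd = c(1, 1, 1)),
               "per cluster")
})

test_that("uniform noise generator fills the unit hypercube with NOISE labels", {
  pc <- sim_uniform_noise(200, 50, seed = 3)
  expect_equal(pc$n_samples, 200L)
  expect_true(all(pc$labels == NOISE_LABEL))
  expect_true(all(pc$coordinates >= 0 & pc$coordinates <= 1))

  ## mean pairwise normalized-L1 distance approaches 1/3 at large D
  v <- dist_matrix(pc, "normalized-l1")$values
  expect_equal(mean(v[upper.tri(v)]), 1 / 3, tolerance = 0.02)

  expect_identical(sim_uniform_noise(5, 2, seed = 9)$coordinates,
                   sim_uniform_noise(5, 2, seed = 9)$coordinates)
  ## single point: valid cloud with no pairs
  expect_equal(sim_uniform_noise(1, 4, seed = 1)$n_samples, 1L)
})

test_that("theory scenario produces exactly coincident clusters", {
  pc <- sim_theory_scenario(5, 20, 50, 30, seed = 5)
  expect_equal(pc$n_samples, 150L)
  d <- dist_matrix(pc, "normalized-l1")$values
  for (m in 1:5) {
    idx <- which(pc$labels == as.character(m))
    expect_true(all(d[idx, idx] == 0))
  }
  expect_identical(sim_theory_scenario(2, 3, 4, 6, seed = 1)$coordinates,
                   sim_theory_scenario(2, 3, 4, 6, seed = 1)$coordinates)
})

test_that("master seed derives independent component sub-streams", {
  ## same master seed, different noise count: cluster block unchanged
  a <- sim_noisy_gaussians(3, 10, 50, 8, seed = 42)
  b <- sim_noisy_gaussians(3, 10, 80, 8, seed = 42)
  expect_identical(a$coordinates[1:30, ], b$coordinates[1:30, ])
})

test_that("measure_shrinkage reports exact identities and the defined pair types", {
  pc <- sim_noisy_gaussians(3, 5, 10, 20, seed = 2)
  d <- dist_matrix(pc, "l2")

  ## identity transform: delta 0, fraction 1 everywhere
  id <- structure(list(values = d$values, k = 1L, source_metric = "l2"),
                  class = "dod_matrix")
  s <- measure_shrinkage(d, id, pc$labels, include_within = TRUE)
  expect_setequal(s$pair_type, c("cluster-cluster", "cluster-noise",
                                 "noise-noise", "within-cluster"))
  expect_true(all(s$delta == 0))
  expect_true(all(s$fraction == 1))

  ## pair counts: 3 clusters x 5 points, 10 noise
  expect_equal(s$n_pairs[s$pair_type == "cluster-cluster"], 3 * 25)
  expect_equal(s$n_pairs[s$pair_type == "cluster-noise"], 15 * 10)
  expect_equal(s$n_pairs[s$pair_type == "noise-noise"], 45)
  expect_equal(s$n_pairs[s$pair_type == "within-cluster"], 3 * 10)

  ## delta = mean_original - mean_transformed exactly, on a real transform
  f <- dod_transform(d, 3)
  s2 <- measure_shrinkage(d, f, pc$labels)
  expect_equal(s2$delta, s2$mean_original - s2$mean_transformed)
  expect_true(all(s2$fraction >= 0 & s2$fraction <= 1))

  ## absent pair types (no noise present) -> warnings and omission
  cl <- sim_gaussian_clusters(2, 4, 5, seed = 1)
  dc <- dist_matrix(cl, "l2")
  fc <- dod_transform(dc, 2)
  w <- capture_warnings(s3 <- measure_shrinkage(dc, fc, cl$labels))
  expect_length(w, 2)
  expect_match(w, "pairs present; type omitted", all = TRUE)
  expect_false("noise-noise" %in% s3$pair_type)

  expect_error(measure_shrinkage(d, f, pc$labels[-1]), "length")
})

test_that("infinite-density clusters are untouched while noise pairs shrink most", {
  pc <- sim_theory_scenario(5, 20, 100, 50, seed = 6)
  d <- dist_matrix(pc, "l2")
  f <- dod_transform(d, 10)
  s <- measure_shrinkage(d, f, pc$labels)
  cc <- s[s$pair_type == "cluster-cluster", ]
  cn <- s[s$pair_type == "cluster-noise", ]
  nn <- s[s$pair_type == "noise-noise", ]
  ## coincident reference neighbors reproduce the original distance exactly
  expect_equal(cc$delta, 0, tolerance = 1e-12)
  expect_gt(nn$delta, cn$delta)
  expect_gt(cn$delta, cc$delta)
})
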