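test_that("closed-form predictions evaluate to their derived values", {
  ## single point: (1/1)^(1/D) = 1 for any D
  expect_equal(expected_nn_distance(1, 7), 1 / 3)
  ## direct arithmetic
  expect_equal(expected_nn_distance(1000, 2), (1 / 3) * 0.001^0.5,
               tolerance = 1e-12)
  expect_equal(expected_nn_distance(1000, 2), 0.01054, tolerance = 1e-3)

  expect_equal(expected_dod_cluster_noise(0.4, 100, 10),
               0.4 - (1 / 6) * 0.01^0.1, tolerance = 1e-12)
  expect_equal(expected_dod_cluster_noise(0.4, 100, 10), 0.2949,
               tolerance = 1e-3)
  expect_equal(expected_dod_cluster_noise(0.7, 1, 33), 0.7 - 1 / 6)

  expect_equal(expected_dod_noise_noise(0.4, 100, 10),
               0.4 - (1 / 3) * 0.01^0.1, tolerance = 1e-12)
  expect_equal(expected_dod_noise_noise(0.4, 100, 10), 0.1897,
               tolerance = 1e-3)

  expect_error(expected_nn_distance(0, 5), "positive integer")
  expect_error(expected_nn_distance(10, -1), "positive integer")
  expect_error(expected_dod_cluster_noise(-0.1, 10, 5), "non-negative")
})

test_that("asymptotes approach 1/6 and 0 monotonically as D grows", {
  for (n in c(10, 200, 5000)) {
    dims <- c(2, 5, 10, 50, 200, 1000, 5000)
    cn <- vapply(dims, function(D) expected_dod_cluster_noise(1 / 3, n, D),
                 numeric(1))
    nn <- vapply(dims, function(D) expected_dod_noise_noise(1 / 3, n, D),
                 numeric(1))
    expect_true(all(diff(cn) < 0))      # decreasing towards 1/6
    expect_true(all(cn > 1 / 6))
    expect_equal(cn[length(cn)], 1 / 6, tolerance = 5e-3)
    expect_true(all(diff(nn) < 0))      # decreasing towards 0
    expect_true(all(nn > 0))
    expect_equal(nn[length(nn)], 0, tolerance = 5e-3)
  }
})

test_that("the cluster-noise / noise-noise gap is exactly (1/6)(1/N)^(1/D)", {
  grid <- expand.grid(n = c(1, 7, 100, 4096), D = c(1, 3, 20, 500),
                      d = c(0, 0.2, 1 / 3, 2))
  for (i in seq_len(nrow(grid))) {
    with(grid[i, ], {
      gap <- expected_dod_cluster_noise(d, n, D) -
        expected_dod_noise_noise(d, n, D)
      ## algebraically exact; numerically limited by cancellation in d - gap
      expect_lt(abs(gap - (1 / 6) * (1 / n)^(1 / D)), 1e-12)
    })
  }
})

test_that("sample-size bound is linear in D and consistent with the gap formula", {
  b <- shrinkage_threshold_bound(20, 0.05)
  expect_equal(b$log_n_max, -20 * log(0.30), tolerance = 1e-12)
  expect_equal(b$log_n_max, 24.08, tolerance = 1e-3)
  expect_equal(b$n_max, exp(b$log_n_max))
  expect_equal(b$log_n_max_printed, -6 * 20 * log(0.05))

  ## doubling D doubles the admissible log N
  expect_equal(shrinkage_threshold_bound(40, 0.05)$log_n_max,
               2 * b$log_n_max)
  ## at theta -> 1/6 the bound collapses to N -> 1
  expect_equal(shrinkage_threshold_bound(10, 1 / 6 - 1e-12)$log_n_max, 0,
               tolerance = 1e-9)
  ## consistency: at N = n_max the gap equals theta
  expect_equal((1 / 6) * (1 / b$n_max)^(1 / 20), 0.05, tolerance = 1e-10)

  expect_error(shrinkage_threshold_bound(10, 0.2), "between 0 and 1/6")
  expect_error(shrinkage_threshold_bound(10, 0), "between 0 and 1/6")
})

test_that("theory_prediction bundles the formulas and guards the metric", {
  tp <- theory_prediction(200, 50)
  expect_equal(tp$shrinkage_gap, expected_nn_distance(200, 50) / 2)
  expect_equal(tp$predicted_f_cluster_noise - tp$predicted_f_noise_noise,
               tp$shrinkage_gap)
  expect_true(tp$expected_nn_distance > 0 &&
                tp$expected_nn_distance <= 1 / 3)

  d <- dist_matrix(matrix(runif(20), 10, 2), "l2")
  expect_error(dodist:::check_theory_metric(d), "normalized-l1")
  dn <- dist_matrix(matrix(runif(20), 10, 2), "normalized-l1")
  expect_true(dodist:::check_theory_metric(dn))
})

mc_nn_distance <- function(n, D, reps) {
  mean(vapply(seq_len(reps), function(r) {
    pc <- sim_uniform_noise(n, D, seed = 1000 * r + 10 * D + n %% 97)
    v <- dist_matrix(pc, "normalized-l1")$values
    diag(v) <- Inf
    mean(apply(v, 1, min))
  }, numeric(1)))
}

test_that("Monte Carlo nearest-neighbor distances track the closed form", {
  ## the closed form is a crude approximation at moderate D (it overshoots
  ## by up to roughly a third there) and tightens as D grows, which is the
  ## regime the shrinkage analysis actually uses
  for (n in c(50, 200, 1000)) {
    for (D in c(2, 5, 10)) {
      obs <- mc_nn_distance(n, D, reps = if (n >= 1000) 2 else 4)
      expect_equal(obs, expected_nn_distance(n, D), tolerance = 0.35)
    }
  }
})

test_that("the nearest-neighbor approximation tightens as dimensionality grows", {
  rel_err <- vapply(c(10, 100, 1000), function(D) {
    obs <- mc_nn_distance(200, D, reps = 3)
    abs(expected_nn_distance(200, D) - obs) / obs
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[3], 0.10)
})
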