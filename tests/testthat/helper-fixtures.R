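## Shared fixture builders; everything is generated in code at test time.

## random valid metric dissimilarity: pairwise L2 distances of a random cloud
random_metric_matrix <- function(n, d = 3, seed = NULL) {
  dodist:::with_seed(seed, {
    dist_matrix(matrix(stats::runif(n * d), n, d), "l2")
  })
}

## random symmetric nonneg matrix with zero diagonal (not necessarily metric)
random_dissimilarity <- function(n, seed = NULL) {
  dodist:::with_seed(seed, {
    m <- matrix(stats::runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    as_dist_matrix(m)
  })
}

expect_valid_dod <- function(f, d = NULL) {
  expect_true(isSymmetric(f$values, tol = 1e-12))
  expect_true(all(diag(f$values) == 0))
  expect_true(all(f$values >= 0))
  if (!is.null(d)) expect_equal(dim(f$values), dim(d$values))
}
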