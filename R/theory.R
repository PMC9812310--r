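#' Expected first-nearest-neighbor distance of uniform points
#'
#' For `N` points scattered uniformly in the unit hypercube in `D`
#' dimensions, the expected normalized-L1 distance from a point to its first
#' nearest neighbor is approximately
#' \deqn{E\{d_{\sigma,\sigma^*}\} \approx \frac{1}{3}\Big(\frac{1}{N}\Big)^{1/D}.}
#' The prefactor 1/3 is the expected normalized-L1 distance between two
#' arbitrary uniform points in the hypercube, approached monotonically as
#' `D` grows at fixed `N` (distance concentration). The formula is an
#' approximation; Monte Carlo agreement is within roughly 15 percent over
#' moderate `N` and `D`.
#'
#' @param n_points Number of scattered points `N` (>= 1).
#' @param dimensionality Feature dimensionality `D` (>= 1).
#' @return Expected nearest-neighbor distance in normalized-L1 units,
#'   in `(0, 1/3]`.
#' @export
expected_nn_distance <- function(n_points, dimensionality) {
  check_count(n_points, "n_points")
  check_count(dimensionality, "dimensionality")
  (1 / 3) * (1 / n_points)^(1 / dimensionality)
}

#' Predicted transformed distance between a cluster point and a noise point
#'
#' Under the idealization that clusters have infinite density (coincident
#' points), centers and noise are uniform in the unit hypercube, distances
#' are normalized L1, and the transform uses a joint neighborhood of size 2
#' (one nearest neighbor per point), the expected transformed cluster-noise
#' distance is
#' \deqn{E\{f_{j,\sigma}\} \approx \tfrac{1}{2}\big(2 d -
#'   \tfrac{1}{3}(1/N)^{1/D}\big) = d - \tfrac{1}{6}(1/N)^{1/D}}
#' for original distance `d`. As `D` grows with `d = 1/3` this tends to 1/6.
#'
#' @param d Original cluster-noise distance (normalized-L1 units, >= 0).
#' @param n_points Number of scattered points `N`.
#' @param dimensionality Feature dimensionality `D`.
#' @return Predicted transformed distance.
#' @export
expected_dod_cluster_noise <- function(d, n_points, dimensionality) {
  check_nonneg(d, "d")
  d - (1 / 2) * expected_nn_distance(n_points, dimensionality)
}

#' Predicted transformed distance between two noise points
#'
#' Same idealization as [expected_dod_cluster_noise()]; both reference
#' neighbors are now nearest neighbors of noise points, so the shrinkage
#' doubles:
#' \deqn{E\{f_{\sigma,\epsilon}\} \approx \tfrac{1}{2}\big(2 d -
#'   \tfrac{2}{3}(1/N)^{1/D}\big) = d - \tfrac{1}{3}(1/N)^{1/D}.}
#' As `D` grows with `d = 1/3` this tends to 0: scattered noise points
#' collapse onto each other while cluster-noise distances stay apart by the
#' gap `(1/6)(1/N)^{1/D}`.
#'
#' @inheritParams expected_dod_cluster_noise
#' @return Predicted transformed distance.
#' @export
expected_dod_noise_noise <- function(d, n_points, dimensionality) {
  check_nonneg(d, "d")
  d - expected_nn_distance(n_points, dimensionality)
}

#' Largest sample size at which the noise-vs-cluster shrinkage gap exceeds a
#' threshold
#'
#' The transformed noise-noise distance lies below the transformed
#' cluster-noise distance by exactly `(1/6)(1/N)^{1/D}`. Requiring this gap
#' to exceed `theta` and solving for `N` gives the operative bound
#' \deqn{\log N < -D \log(6\theta)}
#' (natural logarithm): admissible `log N` is linear in `D`, i.e. the
#' transform tolerates exponentially many noise points as dimensionality
#' grows. A commonly quoted variant of the bound, `log N < -6 D log(theta)`,
#' does not follow from the gap formula; it is returned alongside for
#' reference but the operative bound is the algebraically consistent one.
#'
#' @param dimensionality Feature dimensionality `D`.
#' @param theta Required gap, in `(0, 1/6)` (the gap can never exceed 1/6).
#' @return List with `log_n_max` (operative bound on `log N`), `n_max`
#'   (`exp(log_n_max)`), and `log_n_max_printed` (the `-6 D log(theta)`
#'   variant, for reference).
#' @export
shrinkage_threshold_bound <- function(dimensionality, theta) {
  check_count(dimensionality, "dimensionality")
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta) ||
      theta <= 0 || theta >= 1 / 6) {
    stop("'theta' must lie strictly between 0 and 1/6", call. = FALSE)
  }
  log_n <- -dimensionality * log(6 * theta)
  list(log_n_max = log_n,
       n_max = exp(log_n),
       log_n_max_printed = -6 * dimensionality * log(theta))
}

#' Bundle the closed-form predictions for one scenario
#'
#' Convenience constructor evaluating all predictions at a given scattered
#' sample size and dimensionality, with the mean original distance taken at
#' its large-`D` hypercube value of 1/3 unless supplied.
#'
#' @param n_points Number of scattered points `N`.
#' @param dimensionality Feature dimensionality `D`.
#' @param d Mean original distance; default `1/3`.
#' @return An object of class `theory_prediction`: list with
#'   `expected_nn_distance`, `predicted_f_cluster_noise`,
#'   `predicted_f_noise_noise`, `shrinkage_gap`, plus the inputs.
#' @export
theory_prediction <- function(n_points, dimensionality, d = 1 / 3) {
  nn <- expected_nn_distance(n_points, dimensionality)
  structure(list(
    n_points = n_points,
    dimensionality = dimensionality,
    d = d,
    expected_nn_distance = nn,
    predicted_f_cluster_noise = expected_dod_cluster_noise(d, n_points,
                                                           dimensionality),
    predicted_f_noise_noise = expected_dod_noise_noise(d, n_points,
                                                       dimensionality),
    shrinkage_gap = nn / 2
  ), class = "theory_prediction")
}

#' @export
print.theory_prediction <- function(x, ...) {
  cat(sprintf(
    "theory_prediction (N = %d, D = %d, d = %.4f):\n  E nn distance %.4f | f cluster-noise %.4f | f noise-noise %.4f | gap %.4f\n",
    x$n_points, x$dimensionality, x$d, x$expected_nn_distance,
    x$predicted_f_cluster_noise, x$predicted_f_noise_noise, x$shrinkage_gap))
  invisible(x)
}

## The closed forms assume coincident clusters and the normalized-L1 metric;
## refuse to compare them against matrices built under another metric.
check_theory_metric <- function(dmatrix) {
  m <- if (inherits(dmatrix, "dod_matrix")) dmatrix$source_metric
       else dmatrix$metric
  if (!identical(m, "normalized-l1")) {
    stop(sprintf(
      "theory predictions assume the normalized-l1 metric, but the matrix was built with '%s'",
      m), call. = FALSE)
  }
  invisible(TRUE)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 1 ||
      x != round(x)) {
    stop(sprintf("'%s' must be a positive integer", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative number", name),
         call. = FALSE)
  }
  invisible(x)
}
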