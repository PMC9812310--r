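#' Gaussian cluster generator
#'
#' Draws `m_clusters` cluster centers uniformly in the unit hypercube and
#' `n_per_cluster` points per center from an isotropic Gaussian with the
#' given standard deviation. Labels are the cluster indices `"1" .. "m"`.
#'
#' @param m_clusters Number of clusters.
#' @param n_per_cluster Points per cluster.
#' @param n_features Feature dimensionality `D`.
#' @param sd Gaussian standard deviation; either a scalar or one value per
#'   cluster (a single broader cluster models a lower-density cluster).
#' @param seed Integer seed; identical seeds give identical clouds. `NULL`
#'   draws from the current RNG stream.
#' @param centers Optional `m_clusters x n_features` matrix of centers to use
#'   instead of drawing them.
#' @return A [point_cloud()].
#' @export
sim_gaussian_clusters <- function(m_clusters, n_per_cluster, n_features,
                                  sd = 0.1, seed = NULL, centers = NULL) {
  check_count(m_clusters, "m_clusters")
  check_count(n_per_cluster, "n_per_cluster")
  check_count(n_features, "n_features")
  if (!is.numeric(sd) || any(!is.finite(sd)) || any(sd <= 0)) {
    stop("'sd' must be positive", call. = FALSE)
  }
  if (!length(sd) %in% c(1L, m_clusters)) {
    stop("'sd' must be a scalar or one value per cluster", call. = FALSE)
  }
  sd <- rep_len(sd, m_clusters)
  with_seed(seed, {
    if (is.null(centers)) {
      centers <- matrix(stats::runif(m_clusters * n_features),
                        m_clusters, n_features)
    } else {
      centers <- as.matrix(centers)
      stopifnot(nrow(centers) == m_clusters, ncol(centers) == n_features)
    }
    coords <- do.call(rbind, lapply(seq_len(m_clusters), function(j) {
      matrix(stats::rnorm(n_per_cluster * n_features,
                          mean = rep(centers[j, ], each = n_per_cluster),
                          sd = sd[j]),
             n_per_cluster, n_features)
    }))
    point_cloud(coords, rep(as.character(seq_len(m_clusters)),
                            each = n_per_cluster))
  })
}

#' Uniform hypercube noise generator
#'
#' Draws points uniformly in the `D`-dimensional unit hypercube, all labelled
#' [NOISE_LABEL]. These are the scattering noise points: mutually distant,
#' with no cluster structure, whose pairwise normalized-L1 distances
#' concentrate around 1/3 as `D` grows.
#'
#' @param n_noise Number of noise points.
#' @param n_features Feature dimensionality `D`.
#' @param seed Integer seed, as in [sim_gaussian_clusters()].
#' @return A [point_cloud()].
#' @export
sim_uniform_noise <- function(n_noise, n_features, seed = NULL) {
  check_count(n_noise, "n_noise")
  check_count(n_features, "n_features")
  with_seed(seed, {
    point_cloud(matrix(stats::runif(n_noise * n_features), n_noise,
                       n_features),
                rep(NOISE_LABEL, n_noise))
  })
}

#' Gaussian clusters plus uniform noise
#'
#' The standard benchmark scenario: `m_clusters` Gaussian clusters (sd 0.1 by
#' default) and `n_noise` uniform noise points in the same unit hypercube.
#' The master seed derives independent sub-streams for the cluster and noise
#' components.
#'
#' @inheritParams sim_gaussian_clusters
#' @param n_noise Number of uniform noise points (0 allowed, for noise-free
#'   controls).
#' @return A [point_cloud()] with cluster points first, noise points last.
#' @export
sim_noisy_gaussians <- function(m_clusters, n_per_cluster, n_noise,
                                n_features, sd = 0.1, seed = NULL) {
  clusters <- sim_gaussian_clusters(m_clusters, n_per_cluster, n_features,
                                    sd = sd, seed = sub_seed(seed, 1L))
  if (n_noise == 0) return(clusters)
  bind_point_clouds(clusters,
                    sim_uniform_noise(n_noise, n_features,
                                      seed = sub_seed(seed, 2L)))
}

#' Idealized coincident-cluster scenario
#'
#' The configuration underlying the closed-form predictions: clusters of
#' infinite density, i.e. all points of a cluster exactly coincident at a
#' center drawn uniformly in the unit hypercube, plus uniform noise in the
#' same hypercube. Intra-cluster distances are exactly zero, so the
#' transform preserves cluster-cluster distances exactly whenever the
#' neighborhood size stays below the cluster size.
#'
#' @inheritParams sim_noisy_gaussians
#' @return A [point_cloud()] with cluster points first, noise points last.
#' @export
sim_theory_scenario <- function(m_clusters, n_per_cluster, n_noise,
                                n_features, seed = NULL) {
  check_count(m_clusters, "m_clusters")
  check_count(n_per_cluster, "n_per_cluster")
  check_count(n_noise, "n_noise")
  check_count(n_features, "n_features")
  with_seed(sub_seed(seed, 1L), {
    centers <- matrix(stats::runif(m_clusters * n_features),
                      m_clusters, n_features)
    clusters <- point_cloud(
      centers[rep(seq_len(m_clusters), each = n_per_cluster), , drop = FALSE],
      rep(as.character(seq_len(m_clusters)), each = n_per_cluster))
    bind_point_clouds(clusters,
                      sim_uniform_noise(n_noise, n_features,
                                        seed = sub_seed(seed, 2L)))
  })
}
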