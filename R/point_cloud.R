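#' Label reserved for scattering-noise points
#'
#' Samples carrying this label are treated as noise by the shrinkage
#' summaries, the evaluation harness and the ground-truth scoring.
#' @export
NOISE_LABEL <- "NOISE"

#' Construct a labelled point cloud
#'
#' A point cloud is the raw-feature-space representation of a data set:
#' `n` samples in `d` feature dimensions, each sample carrying exactly one
#' categorical label (a cluster identifier, or [NOISE_LABEL] for scattering
#' noise points).
#'
#' @param coordinates Numeric matrix, one row per sample, one column per
#'   feature. All entries must be finite.
#' @param labels Character vector (or factor) of per-sample labels, one per
#'   row of `coordinates`. `"NOISE"` marks noise points.
#' @return An object of class `point_cloud`: a list with elements
#'   `coordinates`, `labels`, `n_samples`, `n_features`.
#' @examples
#' pc <- point_cloud(matrix(rnorm(20), 10, 2), rep(c("1", "NOISE"), 5))
#' pc$n_samples
#' @export
point_cloud <- function(coordinates, labels) {
  coordinates <- as.matrix(coordinates)
  if (!is.numeric(coordinates)) {
    stop("'coordinates' must be a numeric matrix", call. = FALSE)
  }
  if (nrow(coordinates) < 1L || ncol(coordinates) < 1L) {
    stop("'coordinates' must have at least one row and one column",
         call. = FALSE)
  }
  if (!all(is.finite(coordinates))) {
    stop("'coordinates' contains non-finite values", call. = FALSE)
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(coordinates)) {
    stop(sprintf("'labels' has length %d but 'coordinates' has %d rows",
                 length(labels), nrow(coordinates)), call. = FALSE)
  }
  if (anyNA(labels)) stop("'labels' contains missing values", call. = FALSE)
  structure(
    list(coordinates = coordinates, labels = labels,
         n_samples = nrow(coordinates), n_features = ncol(coordinates)),
    class = "point_cloud"
  )
}

#' @export
print.point_cloud <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("point_cloud: %d samples x %d features\n",
              x$n_samples, x$n_features))
  cat("labels:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Concatenate point clouds
#'
#' Row-binds the coordinates and labels of several point clouds that share
#' the same feature dimensionality, e.g. to combine Gaussian clusters from
#' [sim_gaussian_clusters()] with noise from [sim_uniform_noise()].
#'
#' @param ... `point_cloud` objects with identical `n_features`.
#' @return A single `point_cloud`.
#' @export
bind_point_clouds <- function(...) {
  clouds <- list(...)
  if (length(clouds) == 0L) stop("no point clouds given", call. = FALSE)
  if (!all(vapply(clouds, inherits, logical(1), "point_cloud"))) {
    stop("all arguments must be point_cloud objects", call. = FALSE)
  }
  d <- unique(vapply(clouds, function(p) p$n_features, integer(1)))
  if (length(d) != 1L) {
    stop("point clouds have differing feature dimensionality: ",
         paste(d, collapse = ", "), call. = FALSE)
  }
  point_cloud(do.call(rbind, lapply(clouds, `[[`, "coordinates")),
              unlist(lapply(clouds, `[[`, "labels"), use.names = FALSE))
}

## Run code with a temporary RNG state seeded by `seed`; the caller's
## .Random.seed is restored afterwards so generators do not perturb the
## session RNG stream. seed = NULL runs the code on the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a reproducible sub-seed from a master seed so that the components
## of a composite scenario (cluster centers, cluster points, noise) are
## independently reproducible.
sub_seed <- function(seed, i) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7L + i * 104729) %% .Machine$integer.max)
}
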