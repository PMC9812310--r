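#' Per-pair-type distance shrinkage caused by the transform
#'
#' Compares mean pairwise dissimilarities before and after the DoD
#' transformation, separately for the unordered pair types:
#' \describe{
#'   \item{cluster-cluster}{both points from clusters, but *different*
#'     clusters;}
#'   \item{cluster-noise}{one cluster point, one noise point;}
#'   \item{noise-noise}{both points noise;}
#'   \item{within-cluster}{both points from the *same* cluster (extra
#'     diagnostic, reported when `include_within = TRUE`).}
#' }
#' For each type present in the data it reports the mean original distance
#' `d_bar`, the mean transformed distance `f_bar`, the absolute shrinkage
#' `delta = d_bar - f_bar` and the retained `fraction = f_bar / d_bar`.
#' A larger delta (smaller fraction) means stronger shrinkage; scattering
#' noise pairs shrink the most, which is what isolates them in a subsequent
#' embedding.
#'
#' @param original A `dist_matrix`.
#' @param transformed The matching `dod_matrix` (or any equal-size
#'   `dist_matrix`).
#' @param labels Per-sample labels; [NOISE_LABEL] marks noise.
#' @param include_within Also report the within-cluster pair type.
#' @return A `data.frame` with columns `pair_type`, `n_pairs`,
#'   `mean_original`, `mean_transformed`, `delta`, `fraction`, one row per
#'   pair type that has at least one pair. Types with zero pairs are omitted
#'   with a warning.
#' @export
measure_shrinkage <- function(original, transformed, labels,
                              include_within = FALSE) {
  d <- as_dist_matrix(original)
  fv <- if (inherits(transformed, "dod_matrix")) transformed$values
        else as_dist_matrix(transformed)$values
  labels <- as.character(labels)
  if (length(labels) != d$n) {
    stop(sprintf("'labels' has length %d but matrix has %d rows",
                 length(labels), d$n), call. = FALSE)
  }
  if (!all(dim(fv) == dim(d$values))) {
    stop("original and transformed matrices have different sizes",
         call. = FALSE)
  }
  ut <- upper.tri(d$values)
  noise <- labels == NOISE_LABEL
  pair_noise_i <- matrix(noise, d$n, d$n)            # row point is noise
  pair_noise_j <- matrix(noise, d$n, d$n, byrow = TRUE)
  same_label <- outer(labels, labels, "==")

  masks <- list(
    "cluster-cluster" = !pair_noise_i & !pair_noise_j & !same_label,
    "cluster-noise"   = xor(pair_noise_i, pair_noise_j),
    "noise-noise"     = pair_noise_i & pair_noise_j
  )
  if (include_within) {
    masks[["within-cluster"]] <- !pair_noise_i & !pair_noise_j & same_label
  }
  rows <- lapply(names(masks), function(type) {
    sel <- masks[[type]] & ut
    n_pairs <- sum(sel)
    if (n_pairs == 0L) {
      warning(sprintf("no %s pairs present; type omitted", type),
              call. = FALSE)
      return(NULL)
    }
    d_bar <- mean(d$values[sel])
    f_bar <- mean(fv[sel])
    data.frame(pair_type = type, n_pairs = n_pairs,
               mean_original = d_bar, mean_transformed = f_bar,
               delta = d_bar - f_bar,
               fraction = if (d_bar > 0) f_bar / d_bar else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no pairs of any reportable type (check labels)", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}
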