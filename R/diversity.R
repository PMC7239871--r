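## Chemical-space diversity analysis: column-wise min-max normalization,
## exhaustive pairwise Euclidean distances, and covariance PCA with
## explained-variance reporting.

#' Min-max normalize a descriptor matrix
#'
#' Column-wise `(x - min) / (max - min)`: each column's minimum maps to 0
#' and maximum to 1.  Zero-variance columns must be removed first (see
#' [filterDescriptors()]).  The per-column min/max are attached for inverse
#' mapping and for applying the same scaling to new data.
#'
#' @param mat Structures x descriptors matrix with >= 2 rows.
#' @param stats Optional list with `min` and `range` vectors from a
#'   previous call: apply that scaling instead of fitting a new one (used
#'   to normalize test data with training statistics).
#' @return Matrix with values in `[0, 1]` (when `stats` is refit) and
#'   attribute `"minmax"`.
#' @export
normalizeDescriptors <- function(mat, stats = NULL) {
  mat <- as.matrix(mat)
  if (is.null(stats)) {
    if (nrow(mat) < 2)
      stop("undefined scaling: need at least 2 rows to normalize")
    mn <- apply(mat, 2, min)
    rg <- apply(mat, 2, max) - mn
    if (any(rg == 0))
      stop("zero-range column(s) present; run filterDescriptors() first")
    stats <- list(min = mn, range = rg)
  }
  out <- sweep(sweep(mat, 2, stats$min), 2, stats$range, "/")
  attr(out, "minmax") <- stats
  out
}

#' All pairwise Euclidean distances
#'
#' Exactly `n(n-1)/2` unordered pairs, with summary statistics attached.
#'
#' @param mat Normalized structures x descriptors matrix (>= 2 rows).
#' @return `data.frame` with columns `id_i`, `id_j`, `distance`;
#'   attribute `"summary"` holds min, max and mean.
#' @export
pairwiseDistances <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop("need at least 2 structures")
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  d <- stats::dist(mat)
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
  m <- as.matrix(d)
  out <- data.frame(id_i = ids[pair[, 1]], id_j = ids[pair[, 2]],
                    distance = m[pair])
  attr(out, "summary") <- c(min = min(out$distance), max = max(out$distance),
                            mean = mean(out$distance))
  out
}

#' Principal component analysis of the descriptor space
#'
#' Covariance-based PCA of the (already min-max scaled) descriptor matrix:
#' columns are mean-centered only.  Component signs are fixed by making
#' each component's largest-magnitude loading positive, so results are
#' deterministic.
#'
#' @param mat Structures x descriptors matrix.
#' @param k Number of components, `1 <= k < n`.
#' @return List with `scores` (n x k), `explained` (length-k fractions of
#'   total variance, non-increasing) and `loadings`.
#' @export
descriptorPCA <- function(mat, k = 3) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (k < 1 || k >= n) stop("require 1 <= k < n (n = ", n, ")")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    imax <- which.max(abs(rot[, j]))
    if (rot[imax, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, explained = expl[seq_len(k)], loadings = rot)
}
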