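check_same_length <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("vectors differ in length (%d vs %d)", length(a), length(b)))
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("vectors must be finite")
  invisible(TRUE)
}

#' Manhattan (L1) distance between two vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return sum of absolute coordinate differences.
#' @export
manhattan_distance <- function(a, b) {
  check_same_length(a, b)
  sum(abs(a - b))
}

#' Euclidean (L2) distance between two vectors
#'
#' This is the measure used throughout the clustering objective: the WCD
#' fitness sums *unsquared* Euclidean distances.
#'
#' @param a,b numeric vectors of equal length.
#' @return square root of the sum of squared coordinate differences.
#' @export
euclidean_distance <- function(a, b) {
  check_same_length(a, b)
  sqrt(sum((a - b)^2))
}

#' Cosine similarity between two vectors
#'
#' The inner product divided by the product of the norms, a similarity in
#' `[-1, 1]` (1 for parallel vectors, 0 for orthogonal). Exposed as a
#' similarity, not a distance: no `1 - cos` transform is applied.
#'
#' @param a,b numeric vectors of equal length, neither all-zero.
#' @return cosine of the angle between `a` and `b`.
#' @export
cosine_similarity <- function(a, b) {
  check_same_length(a, b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine_similarity: undefined for an all-zero vector")
  sum(a * b) / (na * nb)
}

# n x k matrix of distances from every data row to every center.
# Per-row accumulation mirrors the C++ fitness kernel exactly
# (sqrt of an extended-precision sum of squares).
distance_matrix <- function(X, centers, metric = "euclidean") {
  k <- nrow(centers)
  out <- matrix(0, nrow(X), k)
  for (t in seq_len(k)) {
    df <- sweep(X, 2L, centers[t, ], "-")
    out[, t] <- switch(metric,
      euclidean = sqrt(rowSums(df * df)),
      manhattan = rowSums(abs(df)),
      stop(sprintf("unsupported metric '%s'", metric)))
  }
  out
}

#' Assign each object to its nearest center
#'
#' Ties are broken deterministically in favor of the lowest center index.
#'
#' @param data a [data_matrix()] (or coercible matrix).
#' @param centers k x d numeric matrix of cluster centers.
#' @param metric `"euclidean"` (default, used by all clustering code) or
#'   `"manhattan"`.
#' @return a [cluster_assignment()].
#' @export
assign_nearest <- function(data, centers, metric = "euclidean") {
  data <- data_matrix(data)
  centers <- as.matrix(centers)
  if (ncol(centers) != data$d)
    stop(sprintf("centers have %d columns but data has %d attributes",
                 ncol(centers), data$d))
  if (!all(is.finite(centers))) stop("centers must be finite")
  dm <- distance_matrix(data$values, centers, metric)
  labels <- max.col(-dm, ties.method = "first")
  cluster_assignment(labels, nrow(centers))
}

#' Within-cluster distance (WCD) objective
#'
#' The fitness minimized by every DE variant in this package: each object is
#' assigned to its nearest center under Euclidean distance, and WCD is the
#' sum over clusters of the *unsquared* Euclidean distances from members to
#' their center,
#' \deqn{\mathrm{wcd} = \sum_{t=1}^{k}\sum_{i=1}^{m_t} \lVert x_i^{(t)} - c_t \rVert.}
#' Note this is not the classical K-Means SSE (which squares the
#' distances); a center with no assigned points contributes zero.
#'
#' @param data a [data_matrix()] (or coercible matrix).
#' @param centers k x d numeric matrix.
#' @return nonnegative scalar.
#' @export
wcd <- function(data, centers) {
  data <- data_matrix(data)
  centers <- as.matrix(centers)
  if (ncol(centers) != data$d)
    stop(sprintf("centers have %d columns but data has %d attributes",
                 ncol(centers), data$d))
  dm <- distance_matrix(data$values, centers, "euclidean")
  sum(do.call(pmin, as.data.frame(dm)))
}
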