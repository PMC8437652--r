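#' Construct a clustering input matrix
#'
#' Wraps an n x d numeric matrix of objects-by-attributes together with its
#' per-attribute bounds (the observed min/max of each column). The bounds
#' define the search box for center-encoded DE individuals, so that every
#' candidate center stays inside the data's attribute ranges.
#'
#' @param x numeric matrix or data frame; rows are objects, columns are
#'   attributes. All entries must be finite.
#' @return an object of class `data_matrix` with fields `values` (the
#'   matrix), `n`, `d`, and `bounds` (d x 2 matrix with columns `min`,
#'   `max`).
#' @examples
#' dm <- data_matrix(matrix(rnorm(20), 5, 4))
#' dm$bounds
#' @export
data_matrix <- function(x) {
  if (inherits(x, "data_matrix")) return(x)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("data_matrix: input must be numeric")
  storage.mode(x) <- "double"
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("data_matrix: need at least one row and one column")
  if (!all(is.finite(x)))
    stop("data_matrix: all entries must be finite (no NA/NaN/Inf)")
  bounds <- cbind(min = apply(x, 2L, min), max = apply(x, 2L, max))
  structure(
    list(values = x, n = nrow(x), d = ncol(x), bounds = bounds),
    class = "data_matrix"
  )
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d objects x %d attributes\n", x$n, x$d))
  cat("attribute ranges:\n")
  print(x$bounds)
  invisible(x)
}

#' Construct a hard cluster assignment
#'
#' A rigid partition of n objects into k clusters: every object belongs to
#' exactly one cluster. Empty clusters are permitted (a center that attracts
#' no points); `counts` exposes per-cluster sizes so callers can detect such
#' degeneracy.
#'
#' @param labels integer vector in `1..k`, one entry per object.
#' @param k number of clusters.
#' @return object of class `cluster_assignment` with `labels`, `k`,
#'   `counts`.
#' @export
cluster_assignment <- function(labels, k) {
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (k < 1L) stop("cluster_assignment: k must be >= 1")
  if (anyNA(labels) || any(labels < 1L | labels > k))
    stop("cluster_assignment: labels must lie in 1..k")
  counts <- tabulate(labels, nbins = k)
  structure(list(labels = labels, k = k, counts = counts),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d objects in %d clusters; sizes: %s\n",
              length(x$labels), x$k, paste(x$counts, collapse = ", ")))
  invisible(x)
}
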