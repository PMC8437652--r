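# Deterministic well-separated center layout: the first k points of the
# integer lattice enumeration scaled by `spacing`, so any two centers are
# at least `spacing` apart in Euclidean distance.
lattice_centers <- function(k, d, spacing) {
  side <- ceiling(k^(1 / d))
  centers <- matrix(0, k, d)
  for (i in seq_len(k)) {
    v <- i - 1L
    for (j in seq_len(d)) {
      centers[i, j] <- (v %% side) * spacing
      v <- v %/% side
    }
  }
  centers
}

#' Generate a separated Gaussian-mixture table with known centers
#'
#' Emulates the clean recovery setting used by the property tests: k
#' isotropic Gaussian components of (near-)equal size whose true centers
#' sit on a lattice with pairwise spacing `separation * sigma`. The true
#' centers and component labels are returned for recovery scoring.
#'
#' @param k number of components.
#' @param n total rows (split as evenly as possible).
#' @param d dimension.
#' @param separation center spacing in noise-standard-deviation units;
#'   must be > 0.
#' @param sigma noise standard deviation (default 1).
#' @param seed optional seed.
#' @return a [labeled_table()] with attribute `"true_centers"` (k x d).
#' @export
gen_gaussian_mixture <- function(k, n, d, separation, sigma = 1,
                                 seed = NULL) {
  if (separation <= 0) stop("gen_gaussian_mixture: separation must be > 0")
  if (k < 1L || n < k) stop("gen_gaussian_mixture: need n >= k >= 1")
  if (!is.null(seed)) set.seed(seed)
  centers <- lattice_centers(k, d, separation * sigma)
  sizes <- rep(n %/% k, k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(seq_len(k), times = sizes)
  X <- centers[labels, , drop = FALSE] +
    matrix(rnorm(n * d, sd = sigma), n, d)
  out <- labeled_table(X, labels = labels)
  attr(out, "true_centers") <- centers
  out
}

#' Generate a binary prescription-by-drug matrix with planted patterns
#'
#' Stand-in for undeposited drug co-occurrence data: rows are
#' prescriptions, columns are drugs. Each of the k patterns owns a disjoint
#' block of drugs; a prescription of pattern t contains each of its own
#' block's drugs with probability `p_in` and every other drug with
#' probability `p_out`. Defaults mirror the scale of the prescription
#' use case this package targets: 270 records, 40 drugs, 7 patterns, with
#' a strong 0.9 / 0.05 contrast.
#'
#' @param k number of planted patterns, `k <= d`.
#' @param n rows (prescriptions).
#' @param d columns (drugs).
#' @param p_in within-pattern drug probability, in (0, 1] .
#' @param p_out background drug probability, in [0, 1).
#' @param seed optional seed.
#' @return a [labeled_table()] of 0/1 features with true pattern labels;
#'   attribute `"blocks"` lists each pattern's drug indices.
#' @export
gen_prescription_matrix <- function(k = 7, n = 270, d = 40,
                                    p_in = 0.9, p_out = 0.05,
                                    seed = NULL) {
  if (k > d) stop("gen_prescription_matrix: need k <= d (disjoint blocks)")
  if (p_in <= 0 || p_in > 1 || p_out < 0 || p_out >= 1)
    stop("gen_prescription_matrix: need p_in in (0,1] and p_out in [0,1)")
  if (!is.null(seed)) set.seed(seed)
  block_size <- d %/% k
  blocks <- split(seq_len(block_size * k),
                  rep(seq_len(k), each = block_size))
  sizes <- rep(n %/% k, k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  labels <- rep(seq_len(k), times = sizes)
  X <- matrix(0, n, d)
  for (i in seq_len(n)) {
    p <- rep(p_out, d)
    p[blocks[[labels[i]]]] <- p_in
    X[i, ] <- as.numeric(runif(d) < p)
  }
  out <- labeled_table(X, labels = labels)
  attr(out, "blocks") <- blocks
  out
}

#' Per-cluster attribute profiles
#'
#' For each cluster, ranks attributes by their within-cluster mean (for 0/1
#' data this is the within-cluster frequency - e.g. how often a drug occurs
#' in a prescription cluster) and reports the top m. Empty clusters are
#' reported with an empty list and a warning.
#'
#' @param result a `clustering_result` obtained on `table`.
#' @param table the [labeled_table()] that was clustered.
#' @param top_m how many attributes to report per cluster.
#' @return object of class `cluster_profile`: a list with one entry per
#'   cluster, each a data frame `(attribute, frequency)` sorted
#'   decreasingly; attribute `"means"` holds the full k x d mean matrix.
#' @export
cluster_profile <- function(result, table, top_m = 5L) {
  stopifnot(inherits(result, "clustering_result"),
            inherits(table, "labeled_table"))
  X <- table$features$values
  labels <- result$assignment$labels
  if (length(labels) != nrow(X))
    stop("cluster_profile: result and table sizes disagree")
  k <- result$assignment$k
  cn <- colnames(X)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(X)))
  means <- matrix(NA_real_, k, ncol(X), dimnames = list(NULL, cn))
  out <- vector("list", k)
  for (t in seq_len(k)) {
    members <- labels == t
    if (!any(members)) {
      warning(sprintf("cluster %d is empty", t))
      out[[t]] <- data.frame(attribute = character(0),
                             frequency = numeric(0))
      next
    }
    m <- colMeans(X[members, , drop = FALSE])
    means[t, ] <- m
    ord <- order(m, decreasing = TRUE)[seq_len(min(top_m, length(m)))]
    out[[t]] <- data.frame(attribute = cn[ord], frequency = m[ord],
                           row.names = NULL)
  }
  structure(out, class = "cluster_profile", means = means,
            sizes = result$assignment$counts)
}

#' @export
print.cluster_profile <- function(x, ...) {
  sizes <- attr(x, "sizes")
  for (t in seq_along(x)) {
    cat(sprintf("cluster %d (%d members):", t, sizes[t]))
    if (nrow(x[[t]]) == 0) { cat(" <empty>\n"); next }
    cat(" ", paste(sprintf("%s (%.2f)", x[[t]]$attribute,
                           x[[t]]$frequency), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Adjusted Rand index between two hard partitions
#'
#' Chance-corrected agreement between two labelings of the same objects:
#' 1 for identical partitions (up to label permutation), about 0 for
#' independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("adjusted_rand_index: label vectors differ in length")
  n <- length(a)
  if (n < 2L) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
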