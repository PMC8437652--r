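#' K-Means configuration
#'
#' @param k number of clusters (must not exceed the number of objects).
#' @param max_iterations cap on Lloyd sweeps.
#' @param seed optional integer seed applied at run start.
#' @param init `"random_points"` (centers drawn as k distinct data rows) or
#'   `"kmeans_pp"` (D-squared seeding, see [kmeans_pp_seed()]).
#' @return object of class `kmeans_config`.
#' @export
kmeans_config <- function(k, max_iterations = 100L, seed = NULL,
                          init = c("random_points", "kmeans_pp")) {
  init <- match.arg(init)
  k <- as.integer(k)
  if (k < 1L) stop("kmeans_config: k must be >= 1")
  if (max_iterations < 1L) stop("kmeans_config: max_iterations must be >= 1")
  structure(list(k = k, max_iterations = as.integer(max_iterations),
                 seed = seed, init = init),
            class = "kmeans_config")
}

#' K-Means++ (D-squared) seeding
#'
#' The first center is a uniformly sampled data row; each subsequent center
#' is a data row sampled with probability proportional to its squared
#' Euclidean distance to the nearest already-chosen center. Chosen rows are
#' excluded from later draws, so the k centers are distinct rows. Uses the
#' current RNG stream.
#'
#' @param data a [data_matrix()] (or coercible matrix).
#' @param k number of centers, `k <= n`.
#' @return k x d matrix of centers (data rows).
#' @export
kmeans_pp_seed <- function(data, k) {
  data <- data_matrix(data)
  k <- as.integer(k)
  if (k > data$n)
    stop(sprintf("kmeans_pp_seed: k = %d exceeds n = %d", k, data$n))
  X <- data$values
  n <- data$n
  chosen <- integer(k)
  chosen[1L] <- sample_int1(n)
  d2 <- rowSums(sweep(X, 2L, X[chosen[1L], ], "-")^2)
  for (t in seq_len(k - 1L)) {
    w <- d2
    w[chosen[seq_len(t)]] <- 0
    tot <- sum(w)
    if (tot > 0) {
      # inverse-CDF draw over the remaining mass
      u <- runif(1L) * tot
      idx <- which(cumsum(w) >= u)[1L]
    } else {
      # all remaining rows coincide with chosen centers: uniform fallback
      avail <- setdiff(seq_len(n), chosen[seq_len(t)])
      idx <- avail[sample_int1(length(avail))]
    }
    chosen[t + 1L] <- idx
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[idx, ], "-")^2))
  }
  X[chosen, , drop = FALSE]
}

#' Classical K-Means (Lloyd's algorithm)
#'
#' Assigns objects to their nearest center (Euclidean), recomputes each
#' center as the mean of its members, and repeats until the assignment is
#' unchanged or the iteration cap is hit. A center left with no members is
#' re-seeded at the point farthest from it. The reported `wcd` is the
#' unsquared-Euclidean within-cluster distance of the final solution - the
#' same objective the DE variants optimize - even though Lloyd's updates
#' minimize the squared objective (SSE); `sse_history` records the SSE
#' after each sweep.
#'
#' @param data a [data_matrix()] (or coercible matrix).
#' @param config a [kmeans_config()].
#' @return a `clustering_result` (see [run_de_kmeans()]) whose `history`
#'   holds the per-sweep WCD and with an extra `sse_history` field.
#' @export
run_kmeans <- function(data, config) {
  data <- data_matrix(data)
  if (!inherits(config, "kmeans_config")) stop("config must be a kmeans_config")
  k <- config$k
  if (k > data$n) stop(sprintf("k = %d exceeds the number of objects (%d)",
                               k, data$n))
  if (!is.null(config$seed)) set.seed(config$seed)
  X <- data$values
  n <- data$n
  centers <- if (config$init == "kmeans_pp") {
    kmeans_pp_seed(data, k)
  } else {
    rows <- integer(k)
    avail <- seq_len(n)
    for (t in seq_len(k)) {          # k distinct random data rows
      j <- sample_int1(length(avail))
      rows[t] <- avail[j]
      avail <- avail[-j]
    }
    X[rows, , drop = FALSE]
  }

  labels <- max.col(-distance_matrix(X, centers), ties.method = "first")
  iterations <- 1L
  wcd_history <- wcd(data, centers)
  sse_history <- sum(distance_matrix(X, centers)[cbind(seq_len(n), labels)]^2)
  repeat {
    for (t in seq_len(k)) {
      members <- labels == t
      if (any(members)) {
        centers[t, ] <- colMeans(X[members, , drop = FALSE])
      } else {
        far <- which.max(rowSums(sweep(X, 2L, centers[t, ], "-")^2))
        centers[t, ] <- X[far, ]
      }
    }
    dm <- distance_matrix(X, centers)
    new_labels <- max.col(-dm, ties.method = "first")
    iterations <- iterations + 1L
    wcd_history <- c(wcd_history, wcd(data, centers))
    sse_history <- c(sse_history, sum(dm[cbind(seq_len(n), new_labels)]^2))
    if (identical(new_labels, labels) || iterations >= config$max_iterations) {
      converged <- identical(new_labels, labels)
      labels <- new_labels
      break
    }
    labels <- new_labels
  }

  structure(list(
    centers = centers,
    assignment = cluster_assignment(labels, k),
    wcd = wcd(data, centers),
    iterations = iterations,
    converged = converged,
    history = wcd_history,
    sse_history = sse_history,
    lambda_history = NULL,
    branch_history = NULL,
    algorithm = if (config$init == "kmeans_pp") "kmeans_pp" else "kmeans"
  ), class = "clustering_result")
}
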