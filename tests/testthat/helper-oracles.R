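# Independent oracle implementations used across the suite. Deliberately
# naive (scalar loops, enumeration) and kept separate from the package's
# vectorized / compiled code paths.

loop_manhattan <- function(a, b) {
  s <- 0
  for (j in seq_along(a)) s <- s + abs(a[j] - b[j])
  s
}

loop_euclidean <- function(a, b) {
  s <- 0
  for (j in seq_along(a)) s <- s + (a[j] - b[j])^2
  sqrt(s)
}

loop_cosine <- function(a, b) {
  num <- 0; na <- 0; nb <- 0
  for (j in seq_along(a)) {
    num <- num + a[j] * b[j]
    na <- na + a[j]^2
    nb <- nb + b[j]^2
  }
  num / (sqrt(na) * sqrt(nb))
}

# exhaustive nearest-center assignment + WCD by scalar loops
loop_wcd <- function(X, centers) {
  tot <- 0
  labels <- integer(nrow(X))
  for (i in seq_len(nrow(X))) {
    best <- Inf; bj <- 0L
    for (t in seq_len(nrow(centers))) {
      dd <- loop_euclidean(X[i, ], centers[t, ])
      if (dd < best) { best <- dd; bj <- t }
    }
    tot <- tot + best
    labels[i] <- bj
  }
  list(wcd = tot, labels = labels)
}

# geometric median of a point set (Weiszfeld iteration, high precision)
weiszfeld <- function(P, tol = 1e-13, iters = 10000L) {
  c0 <- colMeans(P)
  for (it in seq_len(iters)) {
    d <- sqrt(rowSums(sweep(P, 2L, c0)^2))
    if (any(d < 1e-14)) d <- pmax(d, 1e-14)
    w <- 1 / d
    c1 <- colSums(P * w) / sum(w)
    if (max(abs(c1 - c0)) < tol) return(c1)
    c0 <- c1
  }
  c0
}

# exhaustive 2-cluster optimum of the WCD objective with free centers:
# enumerate all bipartitions, place each center at the geometric median
all_bipartition_wcd_min <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 2)) {  # point 1 fixed in cluster 1; B nonempty
    members <- as.logical(bitwAnd(2^(0:(n - 1)), bitwOr(mask * 2, 1)))
    A <- X[members, , drop = FALSE]
    B <- X[!members, , drop = FALSE]
    cA <- weiszfeld(A); cB <- weiszfeld(B)
    v <- sum(sqrt(rowSums(sweep(A, 2L, cA)^2))) +
         sum(sqrt(rowSums(sweep(B, 2L, cB)^2)))
    if (v < best) best <- v
  }
  best
}

# brute-force minimum over all k=2 labelings with mean centers (Lloyd's
# search space), for the k-means lower-bound check
all_bipartition_meanwcd_min <- function(X) {
  n <- nrow(X)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 2)) {
    members <- as.logical(bitwAnd(2^(0:(n - 1)), bitwOr(mask * 2, 1)))
    A <- X[members, , drop = FALSE]
    B <- X[!members, , drop = FALSE]
    v <- sum(sqrt(rowSums(sweep(A, 2L, colMeans(A))^2))) +
         sum(sqrt(rowSums(sweep(B, 2L, colMeans(B))^2)))
    if (v < best) best <- v
  }
  best
}

small_table <- function(seed = 1, n = 12, d = 3) {
  set.seed(seed)
  labeled_table(matrix(rnorm(n * d), n, d),
                labels = rep(1:2, length.out = n))
}
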