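#' Flatten a center matrix into a DE individual
#'
#' Centers are encoded row-major: genes `((t-1)*d + 1) .. (t*d)` hold center
#' t. `decode_centers()` inverts the mapping exactly.
#'
#' @param centers k x d numeric matrix.
#' @return numeric vector of length `k * d`.
#' @export
encode_centers <- function(centers) {
  centers <- as.matrix(centers)
  as.vector(t(centers))
}

#' @rdname encode_centers
#' @param genes numeric vector of length `k * d`.
#' @param k,d decoded shape.
#' @export
decode_centers <- function(genes, k, d) {
  if (length(genes) != k * d)
    stop(sprintf("decode_centers: length %d is not k*d = %d",
                 length(genes), k * d))
  matrix(genes, nrow = k, ncol = d, byrow = TRUE)
}

#' Diversity-switched double mutation
#'
#' The mutation rule of the improved algorithm: when the population
#' diversity indicator is below the threshold (collapsed population) the
#' explorative DE/rand/1 is applied; otherwise the exploitative DE/best/1.
#'
#' @param pop population with evaluated fitness.
#' @param i target index.
#' @param F mutation factor.
#' @param lambda_threshold switch threshold.
#' @param diversity a [diversity_lambda()] result for the current
#'   generation (computed once per generation, not per individual).
#' @return mutant vector; attribute `"branch"` records which strategy fired
#'   (`"rand_1"` or `"best_1"`).
#' @export
double_mutation <- function(pop, i, F, lambda_threshold, diversity) {
  if (diversity$lambda < lambda_threshold) {
    v <- mutate_rand_1(pop, i, F)
    attr(v, "branch") <- "rand_1"
  } else {
    v <- mutate_best_1(pop, i, F)
    attr(v, "branch") <- "best_1"
  }
  v
}

# per-gene bounds for center-encoded individuals: the data's attribute
# ranges tiled k times (row-major layout).
gene_bounds <- function(data, k) {
  b <- data$bounds
  cbind(rep(b[, 1L], times = k), rep(b[, 2L], times = k))
}

resolve_np <- function(config, D) {
  if (!is.null(config$NP)) config$NP else 10L * as.integer(D)
}

strategy_code <- function(strategy) {
  match(strategy, c("rand_1", "best_1", "current_to_best_1",
                    "double_mutation")) - 1L
}

# Pure-R generation loop built from the exported engine operations. It
# consumes the RNG stream identically to the C++ kernel and exists to
# cross-validate it; all production runs go through de_run_cpp().
de_loop_r <- function(data, k, config) {
  X <- data$values
  d <- data$d
  D <- k * d
  NP <- resolve_np(config, D)
  bounds <- gene_bounds(data, k)
  pop <- init_population(bounds, NP)
  pop$fitness <- vapply(seq_len(NP), function(i)
    wcd(data, decode_centers(pop$genes[i, ], k, d)), numeric(1))
  lo <- bounds[, 1L]; hi <- bounds[, 2L]
  scode <- strategy_code(config$strategy)
  history <- lambda_hist <- numeric(0)
  branch_hist <- integer(0)
  best_fit <- min(pop$fitness)
  stag <- 0L
  for (g in seq_len(config$max_generations)) {
    div <- diversity_lambda(pop, rms = config$diversity_rms)
    branch <- if (scode == 3L) {
      if (div$lambda < config$lambda_threshold) 0L else 1L
    } else scode
    newgenes <- pop$genes
    newfit <- pop$fitness
    for (i in seq_len(NP)) {
      v <- switch(branch + 1L,
                  mutate_rand_1(pop, i, config$F),
                  mutate_best_1(pop, i, config$F),
                  mutate_current_to_best_1(pop, i, config$F))
      v <- pmin(pmax(as.numeric(v), lo), hi)
      trial <- as.numeric(binomial_crossover(pop$genes[i, ], v, config$CR))
      ft <- wcd(data, decode_centers(trial, k, d))
      if (ft < pop$fitness[i]) {
        newgenes[i, ] <- trial
        newfit[i] <- ft
      }
    }
    pop$genes <- newgenes
    pop$fitness <- newfit
    pop$generation <- g
    nb <- min(newfit)
    stag <- if (nb == best_fit) stag + 1L else 0L
    best_fit <- nb
    history <- c(history, nb)
    lambda_hist <- c(lambda_hist, div$lambda)
    branch_hist <- c(branch_hist, branch)
    if (stag >= config$stagnation_limit) break
  }
  b <- which.min(pop$fitness)
  list(genes = pop$genes[b, ], fitness = pop$fitness[b],
       history = history, lambda_history = lambda_hist,
       branch_history = branch_hist, iterations = length(history))
}

make_clustering_result <- function(data, k, raw, algorithm, converged) {
  d <- data$d
  centers <- decode_centers(raw$genes, k, d)
  assignment <- assign_nearest(data, centers)
  structure(list(
    centers = centers,
    assignment = assignment,
    wcd = wcd(data, centers),
    iterations = raw$iterations,
    converged = converged,
    history = raw$history,
    lambda_history = raw$lambda_history,
    branch_history = raw$branch_history,
    algorithm = algorithm
  ), class = "clustering_result")
}

run_de_engine <- function(data, k, config, algorithm, use_cpp = TRUE) {
  data <- data_matrix(data)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k > data$n) stop(sprintf("k = %d exceeds the number of objects (%d)",
                               k, data$n))
  if (!inherits(config, "de_config")) stop("config must be a de_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  D <- k * data$d
  NP <- resolve_np(config, D)
  if (use_cpp) {
    bounds <- gene_bounds(data, k)
    pop <- init_population(bounds, NP)
    raw <- de_run_cpp(data$values, k, pop$genes,
                      bounds[, 1L], bounds[, 2L],
                      config$F, config$CR,
                      config$max_generations, config$stagnation_limit,
                      config$lambda_threshold,
                      strategy_code(config$strategy),
                      config$diversity_rms)
  } else {
    raw <- de_loop_r(data, k, config)
  }
  converged <- raw$iterations < config$max_generations
  make_clustering_result(data, k, raw, algorithm, converged)
}

#' Standard DE-K-Means clustering (fixed DE/rand/1)
#'
#' Differential evolution over center-encoded individuals with the fixed
#' DE/rand/1 mutation, binomial crossover and greedy selection, minimizing
#' the unsquared-Euclidean WCD objective. Terminates at the generation cap
#' or once the best fitness has been exactly unchanged for
#' `stagnation_limit` consecutive generations.
#'
#' @param data a [data_matrix()] (or coercible matrix).
#' @param k number of clusters.
#' @param config a [de_config()]; `strategy` is forced to `"rand_1"`.
#' @return object of class `clustering_result` with fields `centers`,
#'   `assignment`, `wcd`, `iterations`, `converged`, `history` (per
#'   generation best WCD), `lambda_history`, `branch_history`.
#' @export
run_de_kmeans <- function(data, k, config = de_config()) {
  config$strategy <- "rand_1"
  run_de_engine(data, k, config, "de_kmeans")
}

#' Improved DE clustering with the diversity-adaptive double mutation
#'
#' Identical machinery to [run_de_kmeans()], but each generation first
#' computes the diversity indicator `lambda(g)` and then mutates every
#' individual with DE/best/1 while the population is still diverse
#' (`lambda >= threshold`) or DE/rand/1 once it has collapsed
#' (`lambda < threshold`), trading exploitation speed early for renewed
#' exploration late.
#'
#' @inheritParams run_de_kmeans
#' @param config a [de_config()]; `strategy` is forced to
#'   `"double_mutation"` unless set to another strategy explicitly via
#'   `keep_strategy`.
#' @param keep_strategy if TRUE, honor `config$strategy` as given instead
#'   of forcing the double mutation (used for sensitivity analyses).
#' @return a `clustering_result`; see [run_de_kmeans()].
#' @export
run_improved <- function(data, k, config = de_config(),
                         keep_strategy = FALSE) {
  if (!keep_strategy) config$strategy <- "double_mutation"
  run_de_engine(data, k, config, "improved")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("<clustering_result> algorithm: %s\n", x$algorithm))
  cat(sprintf("  k = %d clusters, WCD = %.6f\n",
              nrow(x$centers), x$wcd))
  cat(sprintf("  iterations = %d%s; cluster sizes: %s\n", x$iterations,
              if (isTRUE(x$converged)) " (converged)" else "",
              paste(x$assignment$counts, collapse = ", ")))
  invisible(x)
}

#' Benchmark parameter profiles
#'
#' `uci_profile()` is the UCI benchmark setting (F = 0.6, CR = 0.5,
#' NP = 10 x k x d, lambda threshold 0.005, 400-generation stagnation rule,
#' 1500-generation cap). `tcm_profile()` is the prescription-data setting:
#' identical except for a tighter diversity threshold of 0.001 and a
#' 2500-generation cap (the prescription use case fixes k = 7).
#'
#' @param seed optional seed stored in the config.
#' @param NP optional population-size override (default `10 * k * d`,
#'   resolved at run time).
#' @return a [de_config()].
#' @export
uci_profile <- function(seed = NULL, NP = NULL) {
  de_config(F = 0.6, CR = 0.5, NP = NP, lambda_threshold = 0.005,
            max_generations = 1500L, stagnation_limit = 400L, seed = seed)
}

#' @rdname uci_profile
#' @export
tcm_profile <- function(seed = NULL, NP = NULL) {
  de_config(F = 0.6, CR = 0.5, NP = NP, lambda_threshold = 0.001,
            max_generations = 2500L, stagnation_limit = 400L, seed = seed)
}
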