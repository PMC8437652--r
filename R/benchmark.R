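ALGORITHMS <- c("kmeans", "kmeans_pp", "de_kmeans", "improved")

run_one_algorithm <- function(table, k, algo, seed, profile) {
  data <- table$features
  switch(algo,
    kmeans = run_kmeans(data, kmeans_config(k, seed = seed,
                                            init = "random_points")),
    kmeans_pp = run_kmeans(data, kmeans_config(k, seed = seed,
                                               init = "kmeans_pp")),
    de_kmeans = { cfg <- profile; cfg$seed <- seed
                  run_de_kmeans(data, k, cfg) },
    improved = { cfg <- profile; cfg$seed <- seed
                 run_improved(data, k, cfg) },
    stop(sprintf("unknown algorithm '%s' (choose from: %s)",
                 algo, paste(ALGORITHMS, collapse = ", "))))
}

#' Repeated independent clustering runs with table-style summaries
#'
#' The benchmark protocol: each algorithm is run `runs` times
#' independently, run r using seed `base_seed + r`, and the per-algorithm
#' minimum, maximum and mean of the final WCD plus the mean iteration
#' count are aggregated (the classical four-column comparison table).
#'
#' @param table a [labeled_table()].
#' @param k number of clusters.
#' @param algorithms subset of `c("kmeans", "kmeans_pp", "de_kmeans",
#'   "improved")`.
#' @param runs number of independent runs per algorithm.
#' @param base_seed integer; run r uses seed `base_seed + r`.
#' @param profile a [de_config()] applied to the DE algorithms (e.g.
#'   [uci_profile()] or [tcm_profile()]).
#' @param keep_histories if TRUE, per-run convergence histories are
#'   retained in the report (`histories[[algo]][[r]]`).
#' @return object of class `benchmark_report`: `summary` (one row per
#'   algorithm: `algorithm, min_wcd, max_wcd, mean_wcd, mean_iterations`),
#'   `runs` (one row per run: `algorithm, run, seed, wcd, iterations`),
#'   and optionally `histories`.
#' @export
run_benchmark <- function(table, k, algorithms = ALGORITHMS, runs = 40L,
                          base_seed = 0L, profile = uci_profile(),
                          keep_histories = FALSE) {
  stopifnot(inherits(table, "labeled_table"))
  runs <- as.integer(runs)
  if (runs < 1L) stop("run_benchmark: runs must be >= 1")
  bad <- setdiff(algorithms, ALGORITHMS)
  if (length(bad))
    stop(sprintf("unknown algorithm '%s' (choose from: %s)",
                 bad[1L], paste(ALGORITHMS, collapse = ", ")))
  rows <- list()
  histories <- list()
  for (algo in algorithms) {
    hlist <- vector("list", runs)
    for (r in seq_len(runs)) {
      seed <- as.integer(base_seed) + r
      res <- run_one_algorithm(table, k, algo, seed, profile)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = algo, run = r, seed = seed,
        wcd = res$wcd, iterations = res$iterations)
      if (keep_histories) hlist[[r]] <- res$history
    }
    if (keep_histories) histories[[algo]] <- hlist
  }
  per_run <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(algorithms, function(a) {
    sub <- per_run[per_run$algorithm == a, ]
    data.frame(algorithm = a,
               min_wcd = min(sub$wcd),
               max_wcd = max(sub$wcd),
               mean_wcd = mean(sub$wcd),
               mean_iterations = mean(sub$iterations))
  }))
  structure(list(summary = summary, runs = per_run,
                 histories = if (keep_histories) histories else NULL,
                 k = as.integer(k), n_runs = runs,
                 base_seed = as.integer(base_seed)),
            class = "benchmark_report")
}

#' Format a benchmark report as a fixed-column text table
#'
#' Emits the four-column comparison layout (min / max / mean within-class
#' distance, mean iterations) and optionally writes both the text table
#' and a full-precision machine-readable JSON record.
#'
#' @param report a [run_benchmark()] result.
#' @param path optional file stem: writes `<path>.txt` and `<path>.json`.
#' @return the text table as a character vector, invisibly when writing.
#' @export
format_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "benchmark_report"))
  s <- report$summary
  header <- sprintf("%-12s %22s %22s %22s %22s", "Algorithm",
                    "Minimum inner-class", "Maximum inner-class",
                    "Mean inner-class", "Mean iterations")
  lines <- c(header)
  if (nrow(s)) {
    lines <- c(lines, vapply(seq_len(nrow(s)), function(i)
      sprintf("%-12s %22.4f %22.4f %22.4f %22.1f", s$algorithm[i],
              s$min_wcd[i], s$max_wcd[i], s$mean_wcd[i],
              s$mean_iterations[i]), character(1)))
  }
  if (!is.null(path)) {
    writeLines(lines, paste0(path, ".txt"))
    jsonlite::write_json(
      list(k = report$k, n_runs = report$n_runs,
           base_seed = report$base_seed,
           summary = report$summary, runs = report$runs),
      paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Read back a machine-readable benchmark report
#'
#' @param path the `<stem>.json` file written by [format_report()].
#' @return a `benchmark_report` (without histories).
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(summary = as.data.frame(obj$summary),
                 runs = as.data.frame(obj$runs),
                 histories = NULL, k = obj$k, n_runs = obj$n_runs,
                 base_seed = obj$base_seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> k = %d, %d runs per algorithm, base seed %d\n",
              x$k, x$n_runs, x$base_seed))
  cat(format_report(x), sep = "\n")
  invisible(x)
}
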