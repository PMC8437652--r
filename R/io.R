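#' A feature table with optional labels and row names
#'
#' Container returned by [load_table()] and the synthetic generators:
#' numeric features wrapped as a [data_matrix()], plus an optional class
#' label per row (held out from clustering, available for external
#' validation) and optional row identifiers.
#'
#' @param features matrix / data_matrix of numeric attributes.
#' @param labels optional length-n vector of class labels.
#' @param names optional length-n row identifiers.
#' @return object of class `labeled_table`.
#' @export
labeled_table <- function(features, labels = NULL, names = NULL) {
  features <- data_matrix(features)
  if (!is.null(labels) && length(labels) != features$n)
    stop("labeled_table: labels length must equal the number of rows")
  if (!is.null(names) && length(names) != features$n)
    stop("labeled_table: names length must equal the number of rows")
  structure(list(features = features, labels = labels, names = names),
            class = "labeled_table")
}

#' @export
print.labeled_table <- function(x, ...) {
  cat(sprintf("<labeled_table> %d rows x %d attributes%s%s\n",
              x$features$n, x$features$d,
              if (!is.null(x$labels))
                sprintf(", %d label classes", length(unique(x$labels))) else "",
              if (!is.null(x$names)) ", named rows" else ""))
  invisible(x)
}

#' Load a numeric table from CSV or a UCI-style `.data` file
#'
#' UCI `.data` files are comma-separated with no header; CSV files may have
#' a header. One column may be declared the class label (`"first"`,
#' `"last"`, or a column index) and one a row-name column (e.g. the animal
#' name leading each Zoo record). All remaining columns must be numeric; a
#' non-numeric cell raises an error naming its row and column.
#'
#' @param path file path.
#' @param format `"csv"` (header assumed unless `header = FALSE`) or
#'   `"uci_data"` (no header).
#' @param label_column `NULL` (no labels), `"first"`, `"last"`, or index.
#' @param name_column `NULL`, `"first"`, `"last"`, or index.
#' @param delimiter field separator, default `","`.
#' @param header override the format's header default.
#' @return a [labeled_table()].
#' @export
load_table <- function(path, format = c("csv", "uci_data"),
                       label_column = NULL, name_column = NULL,
                       delimiter = ",", header = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("load_table: no such file '%s'", path))
  if (is.null(header)) header <- (format == "csv")
  df <- utils::read.table(path, sep = delimiter, header = header,
                          stringsAsFactors = FALSE, comment.char = "",
                          strip.white = TRUE)
  resolve_col <- function(spec, nc) {
    if (is.null(spec)) return(NULL)
    if (identical(spec, "first")) return(1L)
    if (identical(spec, "last")) return(nc)
    as.integer(spec)
  }
  nc <- ncol(df)
  lc <- resolve_col(label_column, nc)
  mc <- resolve_col(name_column, nc)
  labels <- if (!is.null(lc)) df[[lc]] else NULL
  names_ <- if (!is.null(mc)) as.character(df[[mc]]) else NULL
  drop <- c(lc, mc)
  feat <- if (length(drop)) df[, -drop, drop = FALSE] else df
  for (j in seq_along(feat)) {
    col <- feat[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf(
          "load_table: non-numeric feature cell at row %d, column %d ('%s')",
          bad[1L], j, col[bad[1L]]))
      feat[[j]] <- num
    }
  }
  if (anyNA(feat))
    stop("load_table: missing values are not supported")
  labeled_table(as.matrix(feat), labels = labels, names = names_)
}

#' Write a labeled table to CSV
#'
#' Features first, then optional `label` and `name` columns; reloading with
#' [load_table()] reproduces the features exactly (values are written with
#' full precision).
#'
#' @param table a [labeled_table()].
#' @param path output file.
#' @export
write_table_csv <- function(table, path) {
  stopifnot(inherits(table, "labeled_table"))
  df <- as.data.frame(table$features$values)
  colnames(df) <- paste0("x", seq_len(ncol(df)))
  if (!is.null(table$labels)) df$label <- table$labels
  if (!is.null(table$names)) df$name <- table$names
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a convergence history as a two-column CSV
#'
#' Writes `(generation, best_wcd)` rows - the data behind per-run
#' convergence curves.
#'
#' @param result a `clustering_result`.
#' @param path output file.
#' @export
write_history_csv <- function(result, path) {
  stopifnot(inherits(result, "clustering_result"))
  df <- data.frame(generation = seq_along(result$history),
                   best_wcd = result$history)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Path to a bundled UCI-layout dataset
#'
#' `"iris"` is the literal UCI distribution of Fisher's iris data,
#' including the two historically erroneous records (rows 35 and 38) that
#' differ from the corrected version shipped with R; the benchmark
#' literature this package reproduces used the literal file. `"wine"` is
#' the UCI wine recognition data (class label in the first column).
#'
#' @param name `"iris"`, `"wine"`, or `"zoo"` (zoo is not bundled; the
#'   returned path exists only if the user has placed the file there).
#' @return file path inside the installed package.
#' @export
builtin_dataset_path <- function(name = c("iris", "wine", "zoo")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".data"), package = "decluster")
}

#' Load a bundled benchmark dataset
#'
#' @param name `"iris"`, `"wine"`, or `"zoo"`.
#' @return a [labeled_table()].
#' @export
load_builtin <- function(name = c("iris", "wine", "zoo")) {
  name <- match.arg(name)
  path <- builtin_dataset_path(name)
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("dataset '%s' is not available (file not bundled)", name))
  switch(name,
    iris = load_table(path, "uci_data", label_column = "last"),
    wine = load_table(path, "uci_data", label_column = "first"),
    zoo  = load_table(path, "uci_data", label_column = "last",
                      name_column = "first"))
}
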