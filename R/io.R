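# Delimited-text I/O shared by the functions and the command-line script.
# Data tables are samples x variables with a mandatory header row; tab- or
# comma-separation is auto-detected. Variants are identified positionally
# (the first n_gv columns).

#' Read a samples x variables data table
#'
#' @param path delimited text file, header row mandatory; tab- or
#'   comma-separated (auto-detected from the header line).
#' @return numeric matrix with column names.
#' @export
read_data_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         check.names = FALSE)
  x <- as.matrix(d)
  if (!is.numeric(x)) stop("data table must be numeric")
  x
}

#' Write a data matrix as tab-separated text
#' @param x matrix with column names.
#' @param path output file.
#' @export
write_data_matrix <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an adjacency matrix as CSV
#'
#' Parents in rows, children in columns (see [as_adjacency()]); lets
#' external tools' outputs be scored with the same machinery.
#'
#' @param g a `mixed_graph` (for writing).
#' @param path CSV file.
#' @export
write_adjacency <- function(g, path) {
  utils::write.csv(as_adjacency(g), path, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @param n_gv number of leading variant nodes (for reading).
#' @return `read_adjacency` returns a `mixed_graph`.
#' @export
read_adjacency <- function(path, n_gv = 0L) {
  a <- as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
  graph_from_adjacency(a, n_gv)
}

#' Write the independence-test log of a fit
#'
#' Tab-separated audit log: one line per test with the pair, conditioning
#' set, correlation, statistic, p-value, the LOND level used and the
#' decision, preceded by `#`-prefixed metadata lines (parameters and final
#' controller state).
#'
#' @param fit an `mrpc` object.
#' @param path output file.
#' @export
write_test_log <- function(fit, path) {
  con <- file(path, "w"); on.exit(close(con))
  p <- fit$params
  writeLines(c(
    sprintf("# fdr: %g", p$fdr), sprintf("# a: %d", p$a),
    sprintf("# c: %.10g", fit$lond$c), sprintf("# beta: %g", p$beta),
    sprintf("# max_cond: %d", p$max_cond),
    sprintf("# n: %s", if (is.null(p$n)) "NA" else p$n),
    sprintf("# tests: %d rejections: %d", fit$lond$i, fit$lond$D)), con)
  utils::write.table(fit$tests, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
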