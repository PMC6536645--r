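# Direction-aware scoring of inferred graphs against ground truth:
# recall/precision with half credit for present-but-misdirected edges,
# empirical type-I error under null topologies, bootstrap edge
# probabilities, and grid summaries.

#' Direction-aware recall and precision
#'
#' Each true edge earns credit 1 when the inferred graph contains it with
#' the correct direction, 0.5 when the edge is present but mis- or
#' un-directed, and 0 when absent. An undirected true edge scores 1 only
#' against an undirected/bidirected inferred edge and 0.5 against either
#' single orientation (direction over-committed). Recall divides the total
#' credit by the number of true edges; precision divides the same credit by
#' the number of inferred edges. With `exclude_variant_edges = TRUE` (the
#' default, matching the convention that variant edges are always correctly
#' oriented once present) every edge touching a variant is dropped from
#' both counts — including spurious inferred variant edges.
#'
#' @param truth,inferred `mixed_graph`s over the same node set.
#' @param exclude_variant_edges drop variant-touching edges from scoring.
#' @return object of class `score_report`: list with `recall`, `precision`,
#'   `n_true`, `n_inferred` (after exclusion) and `ledger`, a per-true-edge
#'   credit table. A precision denominator of zero yields `NA`.
#' @examples
#' truth <- canned_topology("M1")$graph
#' inferred <- set_edge(truth, "V1", "T2", "directed")
#' recall_precision(truth, inferred)  # recall 1, precision 1
#' @export
recall_precision <- function(truth, inferred, exclude_variant_edges = TRUE) {
  if (!setequal(truth$nodes, inferred$nodes))
    stop("truth and inferred graphs must share a node set")
  inferred <- reorder_nodes(inferred, truth$nodes)
  is_variant_edge <- function(g, from, to)
    g$roles[node_index(g, from)] == "variant" ||
    g$roles[node_index(g, to)] == "variant"
  te <- graph_edges(truth)
  ie <- graph_edges(inferred)
  if (exclude_variant_edges) {
    keep_t <- !mapply(is_variant_edge, te$from, te$to,
                      MoreArgs = list(g = truth))
    keep_i <- !mapply(is_variant_edge, ie$from, ie$to,
                      MoreArgs = list(g = inferred))
    te <- te[as.logical(keep_t), , drop = FALSE]
    ie <- ie[as.logical(keep_i), , drop = FALSE]
  }
  credit <- numeric(nrow(te)); reason <- character(nrow(te))
  for (k in seq_len(nrow(te))) {
    m_inf <- edge_mark(inferred, te$from[k], te$to[k])
    if (te$mark[k] == "directed") {
      if (m_inf == "forward") { credit[k] <- 1; reason[k] <- "correct direction" }
      else if (m_inf == "absent") { credit[k] <- 0; reason[k] <- "missing" }
      else { credit[k] <- 0.5
             reason[k] <- if (m_inf == "backward") "wrong direction"
                          else "undirected" }
    } else {  # true edge undirected/bidirected
      if (m_inf %in% c("undirected", "bidirected")) {
        credit[k] <- 1; reason[k] <- "correct (undirected)"
      } else if (m_inf == "absent") { credit[k] <- 0; reason[k] <- "missing" }
      else { credit[k] <- 0.5; reason[k] <- "direction over-committed" }
    }
  }
  n_true <- nrow(te); n_inf <- nrow(ie)
  structure(list(
    recall = if (n_true > 0) sum(credit) / n_true else NA_real_,
    precision = if (n_inf > 0) sum(credit) / n_inf else NA_real_,
    n_true = n_true, n_inferred = n_inf,
    ledger = data.frame(from = te$from, to = te$to, true_mark = te$mark,
                        credit = credit, reason = reason,
                        stringsAsFactors = FALSE)),
    class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat(sprintf("recall = %s, precision = %s (%d true, %d inferred edges)\n",
              format(x$recall), format(x$precision), x$n_true, x$n_inferred))
  if (nrow(x$ledger)) print(x$ledger, row.names = FALSE)
  invisible(x)
}

#' Empirical type-I error under a null topology
#'
#' Under the null three-node models (no T1-T2 edge) the relevant error is
#' how often any edge — whatever its mark — is inferred between the two
#' phenotypes, ignoring variant edges.
#'
#' @param truth_name `"M0"` or `"M3"`.
#' @param inferred_graphs list of `mixed_graph`s from replicate analyses.
#' @return fraction of replicates containing a T1-T2 edge.
#' @export
empirical_type1 <- function(truth_name, inferred_graphs) {
  if (!truth_name %in% c("M0", "M3"))
    stop("empirical type-I error is defined for the null topologies M0/M3")
  mean(vapply(inferred_graphs, function(g) has_edge(g, "T1", "T2"), NA))
}

#' Bootstrap edge probabilities
#'
#' Resamples individuals with replacement `B` times, refits the learner on
#' each bootstrap sample, and reports for every ordered node pair the
#' fraction of bootstrap graphs containing that directed edge. An
#' undirected or bidirected inferred edge contributes 0.5 to each
#' direction.
#'
#' @param data samples x variables matrix (variants first).
#' @param n_gv number of leading variant columns.
#' @param B number of bootstrap resamples.
#' @param fdr,beta,a learner settings, see [mrpc()].
#' @param seed integer seed for the resampling.
#' @return square matrix of proportions (rows: parent, cols: child).
#' @export
bootstrap_edge_probs <- function(data, n_gv, B = 200L, fdr = 0.05,
                                 beta = 0, a = 2L, seed = NULL) {
  x <- as.matrix(data)
  stopifnot(B >= 1)
  if (!is.null(seed)) { old <- save_rng(); on.exit(restore_rng(old)); set.seed(seed) }
  p <- ncol(x)
  acc <- matrix(0, p, p, dimnames = list(colnames(x), colnames(x)))
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(x), replace = TRUE)
    fit <- mrpc(x[idx, , drop = FALSE], n_gv = n_gv, fdr = fdr, beta = beta,
                a = a)
    m <- fit$graph$marks
    acc[m == MARK_DIR] <- acc[m == MARK_DIR] + 1
    sym <- m == MARK_UNDIR | m == MARK_BIDIR
    acc[sym] <- acc[sym] + 0.5
  }
  acc / B
}

#' Benchmark a learner over the topology x signal x sample-size grid
#'
#' For every combination of topology, effect size and sample size, simulates
#' `reps` datasets, fits [mrpc()] and scores it against the truth with
#' [recall_precision()]; per-scenario means are returned.
#'
#' @param topologies character vector of [canned_topology()] names.
#' @param gammas,ns effect sizes and sample sizes (defaults: the standard
#'   12-cell grid).
#' @param reps replicates per scenario.
#' @param fdr,beta,a learner settings.
#' @param seed integer; each replicate derives its own sub-seed from it.
#' @param verbose print one progress line per scenario to standard error.
#' @return data frame with one row per scenario: `topology`, `gamma`, `n`,
#'   `recall`, `precision` (means over replicates, `NA`-removed for
#'   precision when a replicate inferred no edges).
#' @export
benchmark_grid <- function(topologies = c("M1", "M2", "M4", "multi_parent",
                                          "star", "layered"),
                           gammas = c(0.2, 0.5, 1.0),
                           ns = c(50L, 200L, 500L, 1000L),
                           reps = 50L, fdr = 0.05, beta = 0, a = 2L,
                           seed = 1L, verbose = FALSE) {
  grid <- expand.grid(topology = topologies, gamma = gammas, n = ns,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$recall <- NA_real_; grid$precision <- NA_real_
  for (s in seq_len(nrow(grid))) {
    topo <- canned_topology(grid$topology[s], gamma = grid$gamma[s])
    rec <- pre <- numeric(reps)
    for (r in seq_len(reps)) {
      d <- simulate_dataset(topo, n = grid$n[s],
                            seed = seed * 10000L + s * 100L + r)
      fit <- mrpc(d, n_gv = sum(topo$graph$roles == "variant"),
                  fdr = fdr, beta = beta, a = a)
      sc <- recall_precision(topo$graph, fit$graph)
      rec[r] <- sc$recall; pre[r] <- sc$precision
    }
    grid$recall[s] <- mean(rec, na.rm = TRUE)
    grid$precision[s] <- mean(pre, na.rm = TRUE)
    if (verbose)
      message(sprintf("[%d/%d] %s gamma=%g n=%d: recall %.3f precision %.3f",
                      s, nrow(grid), grid$topology[s], grid$gamma[s],
                      grid$n[s], grid$recall[s], grid$precision[s]))
  }
  grid
}

#' Summarize per-scenario scores
#'
#' @param scores data frame from [benchmark_grid()] (or any frame with
#'   `recall` and `precision` columns, one row per scenario).
#' @return data frame with the median and standard deviation of each metric
#'   across scenarios.
#' @export
grid_summary <- function(scores) {
  data.frame(
    metric = c("recall", "precision"),
    median = c(stats::median(scores$recall, na.rm = TRUE),
               stats::median(scores$precision, na.rm = TRUE)),
    sd = c(stats::sd(scores$recall, na.rm = TRUE),
           stats::sd(scores$precision, na.rm = TRUE)))
}
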