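# Ground-truth topology catalog used by the simulator and scored by the
# evaluator.

#' Construct a topology specification
#'
#' Bundles a ground-truth mixed graph with the generative parameters the
#' simulator needs: one regression coefficient per (directed or undirected)
#' edge, an intercept, per-phenotype noise SD and per-variant minor allele
#' frequency.
#'
#' @param graph a `mixed_graph` (must be acyclic under every orientation of
#'   its undirected edges).
#' @param gamma scalar coefficient applied to every edge, or a named numeric
#'   vector keyed `"from->to"` / `"from--to"`.
#' @param gamma0 intercept of the linear model for every phenotype.
#' @param sigma noise standard deviation; scalar or one value per phenotype.
#' @param q minor allele frequency; scalar or one value per variant.
#' @return an object of class `topology_spec`.
#' @export
topology_spec <- function(graph, gamma = 1, gamma0 = 0, sigma = 1, q = 0.45) {
  validate_graph(graph)
  if (!is_acyclic(graph)) stop("topology graph must be acyclic")
  ed <- graph_edges(graph)
  keys <- edge_keys(ed)
  if (length(gamma) == 1L && is.null(names(gamma))) {
    coefficients <- stats::setNames(rep(as.numeric(gamma), nrow(ed)), keys)
  } else {
    if (!setequal(names(gamma), keys))
      stop("gamma must name every edge: ", paste(keys, collapse = ", "))
    coefficients <- gamma[keys]
  }
  n_ph <- sum(graph$roles == "phenotype")
  n_v <- sum(graph$roles == "variant")
  sigma <- rep_len(as.numeric(sigma), n_ph)
  if (any(sigma <= 0)) stop("sigma must be > 0")
  q <- rep_len(as.numeric(q), max(n_v, 1L))[seq_len(n_v)]
  if (length(q) && any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  structure(list(graph = graph, coefficients = coefficients,
                 gamma0 = as.numeric(gamma0), sigma = sigma, q = q),
            class = "topology_spec")
}

edge_keys <- function(ed) {
  sep <- ifelse(ed$mark == "directed", "->", "--")
  paste0(ed$from, sep, ed$to)
}

#' @export
print.topology_spec <- function(x, ...) {
  cat("Topology:\n")
  print(x$graph)
  cat("gamma0 =", x$gamma0, "; sigma =", paste(unique(x$sigma), collapse = ","),
      "; q =", paste(unique(x$q), collapse = ","), "\n")
  cat("edge coefficients:",
      paste(names(x$coefficients), x$coefficients, sep = " = ",
            collapse = "; "), "\n")
  invisible(x)
}

#' Canned ground-truth topologies
#'
#' The five basic three-node models (`M0`-`M4`: one variant V1 plus two
#' phenotypes T1, T2), three common regulatory motifs (`multi_parent`,
#' `star`, `layered`) and a seedable random `complex` DAG with more than 20
#' nodes and variant nodes as sources.
#'
#' The five basic models:
#' \describe{
#'   \item{M0}{V1 -> T1, T2 isolated (null: T1 and T2 marginally independent).}
#'   \item{M1}{V1 -> T1 -> T2 (canonical causal chain).}
#'   \item{M2}{V1 -> T1 <- T2 (phenotype collider).}
#'   \item{M3}{V1 -> T1, V1 -> T2 (common variant cause, no T1-T2 edge).}
#'   \item{M4}{V1 -> T1, V1 -> T2, T1 -- T2 (common cause plus direct
#'     dependence; the T1-T2 edge is undirected).}
#' }
#'
#' The exact wiring of the three motif topologies is not uniquely fixed by
#' their common depictions; the defaults used here are documented stand-ins
#' (configurable by building a [topology_spec()] from any [mixed_graph()]):
#' `multi_parent` is V1 -> T1, V1 -> T2, T1 -> T3, T2 -> T3 (one node with
#' two parents); `star` is V1 -> T1 with T1 -> T2..T5; `layered` is
#' V1 -> T1; T1 -> T2, T3; T2 -> T4, T5; T3 -> T6, T7.
#'
#' `complex` draws an Erdos-Renyi-style random DAG over a fixed node order
#' (2 variant sources first) with edge probability set for a mean total
#' degree of about 2; reproducible given `seed`.
#'
#' @param name topology name.
#' @param gamma edge coefficient(s), see [topology_spec()].
#' @param n_nodes node count, used only for `complex` (must be > 20).
#' @param seed integer seed, used only for `complex`.
#' @param ... further arguments (`gamma0`, `sigma`, `q`) for [topology_spec()].
#' @return a `topology_spec`.
#' @examples
#' canned_topology("M1")
#' canned_topology("complex", n_nodes = 22, seed = 1)
#' @export
canned_topology <- function(name = c("M0", "M1", "M2", "M3", "M4",
                                     "multi_parent", "star", "layered",
                                     "complex"),
                            gamma = 1, n_nodes = 22L, seed = 1L, ...) {
  name <- match.arg(name)
  g <- switch(
    name,
    M0 = set_edge(mixed_graph(c("V1", "T1", "T2"), 1L), "V1", "T1", "directed"),
    M1 = {
      g <- mixed_graph(c("V1", "T1", "T2"), 1L)
      g <- set_edge(g, "V1", "T1", "directed")
      set_edge(g, "T1", "T2", "directed")
    },
    M2 = {
      g <- mixed_graph(c("V1", "T1", "T2"), 1L)
      g <- set_edge(g, "V1", "T1", "directed")
      set_edge(g, "T2", "T1", "directed")
    },
    M3 = {
      g <- mixed_graph(c("V1", "T1", "T2"), 1L)
      g <- set_edge(g, "V1", "T1", "directed")
      set_edge(g, "V1", "T2", "directed")
    },
    M4 = {
      g <- mixed_graph(c("V1", "T1", "T2"), 1L)
      g <- set_edge(g, "V1", "T1", "directed")
      g <- set_edge(g, "V1", "T2", "directed")
      set_edge(g, "T1", "T2", "undirected")
    },
    multi_parent = {
      g <- mixed_graph(c("V1", paste0("T", 1:3)), 1L)
      g <- set_edge(g, "V1", "T1", "directed")
      g <- set_edge(g, "V1", "T2", "directed")
      g <- set_edge(g, "T1", "T3", "directed")
      set_edge(g, "T2", "T3", "directed")
    },
    star = {
      g <- mixed_graph(c("V1", paste0("T", 1:5)), 1L)
      g <- set_edge(g, "V1", "T1", "directed")
      for (k in 2:5) g <- set_edge(g, "T1", paste0("T", k), "directed")
      g
    },
    layered = {
      g <- mixed_graph(c("V1", paste0("T", 1:7)), 1L)
      g <- set_edge(g, "V1", "T1", "directed")
      g <- set_edge(g, "T1", "T2", "directed")
      g <- set_edge(g, "T1", "T3", "directed")
      g <- set_edge(g, "T2", "T4", "directed")
      g <- set_edge(g, "T2", "T5", "directed")
      g <- set_edge(g, "T3", "T6", "directed")
      set_edge(g, "T3", "T7", "directed")
    },
    complex = complex_graph(n_nodes, seed)
  )
  topology_spec(g, gamma = gamma, ...)
}

# Random DAG over a fixed topological order: 2 variant sources followed by
# phenotypes; edge probability targets a mean total degree of ~2 (expected
# edge count ~ n_nodes). Each phenotype is guaranteed at least one parent so
# no node is trivially isolated.
complex_graph <- function(n_nodes, seed) {
  n_nodes <- as.integer(n_nodes)
  if (n_nodes <= 20L)
    stop("the complex topology requires n_nodes > 20")
  n_gv <- 2L
  nodes <- c(paste0("V", seq_len(n_gv)), paste0("T", seq_len(n_nodes - n_gv)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  g <- mixed_graph(nodes, n_gv)
  # admissible ordered pairs: i < j in node order, j a phenotype
  pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] > n_gv, , drop = FALSE]
  prob <- min(1, n_nodes / nrow(pairs))
  keep <- stats::runif(nrow(pairs)) < prob
  for (r in which(keep))
    g <- set_edge(g, pairs[r, 1], pairs[r, 2], "directed")
  for (j in (n_gv + 1L):n_nodes) {
    if (!any(g$marks[seq_len(j - 1L), j] == MARK_DIR)) {
      parent <- sample.int(j - 1L, 1L)
      g <- set_edge(g, parent, j, "directed")
    }
  }
  g
}
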