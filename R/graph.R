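# Mixed-graph data model shared by the learner, the simulator and the scorer.
#
# Internal mark codes, stored in a square integer matrix `marks`:
#   0 absent, 1 undirected, 2 directed row -> col, 3 bidirected.
# Consistency: codes 0/1/3 are symmetric; a directed edge i -> j is stored as
# marks[i, j] == 2 with marks[j, i] == 0, so edge presence must always be
# queried through has_edge()/edge_mark(), never by testing a single cell.

MARK_ABSENT <- 0L
MARK_UNDIR  <- 1L
MARK_DIR    <- 2L
MARK_BIDIR  <- 3L

#' Create an empty mixed graph
#'
#' A mixed graph holds a fixed, ordered node set in which genetic variants
#' occupy the first positions, and an edge-mark structure supporting absent,
#' undirected, directed and bidirected edges. Variant nodes may never have an
#' arrowhead pointing into them: under Mendelian randomization genotypes are
#' causes, not effects, of molecular phenotypes.
#'
#' @param nodes character vector of unique node names, variants first.
#' @param n_gv number of leading nodes that are genetic variants.
#' @return an object of class `mixed_graph` with elements `nodes`, `roles`
#'   (factor with levels `variant`, `phenotype`) and `marks` (integer matrix).
#' @examples
#' g <- mixed_graph(c("V1", "T1", "T2"), n_gv = 1)
#' g <- set_edge(g, "V1", "T1", "directed")
#' edge_mark(g, "V1", "T1")
#' @export
mixed_graph <- function(nodes, n_gv = 0L) {
  nodes <- as.character(nodes)
  stopifnot(length(nodes) >= 1L, !anyDuplicated(nodes),
            n_gv >= 0L, n_gv <= length(nodes))
  p <- length(nodes)
  roles <- factor(rep(c("variant", "phenotype"), c(n_gv, p - n_gv)),
                  levels = c("variant", "phenotype"))
  marks <- matrix(MARK_ABSENT, p, p, dimnames = list(nodes, nodes))
  structure(list(nodes = nodes, roles = roles, marks = marks),
            class = "mixed_graph")
}

node_index <- function(g, x) {
  if (is.character(x)) {
    i <- match(x, g$nodes)
    if (anyNA(i)) stop("unknown node(s): ", paste(x[is.na(i)], collapse = ", "))
    i
  } else as.integer(x)
}

#' Set or remove an edge in a mixed graph
#'
#' @param g a `mixed_graph`.
#' @param from,to node names or indices. For `type = "directed"` the edge is
#'   oriented `from -> to`; for the symmetric types the order is irrelevant.
#' @param type one of `"absent"`, `"undirected"`, `"directed"`, `"bidirected"`.
#' @return the modified graph.
#' @export
set_edge <- function(g, from, to, type = c("undirected", "directed",
                                           "bidirected", "absent")) {
  type <- match.arg(type)
  i <- node_index(g, from); j <- node_index(g, to)
  if (i == j) stop("self edges are not allowed")
  code <- switch(type, absent = MARK_ABSENT, undirected = MARK_UNDIR,
                 directed = MARK_DIR, bidirected = MARK_BIDIR)
  if (code == MARK_DIR) {
    if (g$roles[j] == "variant")
      stop("cannot orient an edge into variant node '", g$nodes[j], "'")
    g$marks[i, j] <- MARK_DIR
    g$marks[j, i] <- MARK_ABSENT
  } else {
    g$marks[i, j] <- code
    g$marks[j, i] <- code
  }
  g
}

#' Query the mark between two nodes
#'
#' @param g a `mixed_graph`.
#' @param from,to node names or indices.
#' @return `"absent"`, `"undirected"`, `"bidirected"`, `"forward"`
#'   (`from -> to`) or `"backward"` (`to -> from`).
#' @export
edge_mark <- function(g, from, to) {
  i <- node_index(g, from); j <- node_index(g, to)
  m <- g$marks[i, j]; rm_ <- g$marks[j, i]
  if (m == MARK_DIR) return("forward")
  if (rm_ == MARK_DIR) return("backward")
  switch(m + 1L, "absent", "undirected", , "bidirected")
}

#' @rdname edge_mark
#' @export
has_edge <- function(g, from, to) {
  i <- node_index(g, from); j <- node_index(g, to)
  g$marks[i, j] != MARK_ABSENT || g$marks[j, i] != MARK_ABSENT
}

# logical symmetric adjacency (any mark)
adjacency_any <- function(g) {
  g$marks != MARK_ABSENT | t(g$marks) != MARK_ABSENT
}

#' List the edges of a mixed graph
#'
#' @param g a `mixed_graph`.
#' @return a data frame with columns `from`, `to`, `mark`
#'   (`undirected` / `directed` / `bidirected`). Directed edges are listed
#'   `from -> to`; symmetric edges are listed once with `from` before `to` in
#'   the node order.
#' @export
graph_edges <- function(g) {
  p <- length(g$nodes)
  from <- character(0); to <- character(0); mark <- character(0)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    m <- g$marks[i, j]
    if (m == MARK_DIR) {
      from <- c(from, g$nodes[i]); to <- c(to, g$nodes[j])
      mark <- c(mark, "directed")
    } else if (i < j && m %in% c(MARK_UNDIR, MARK_BIDIR)) {
      from <- c(from, g$nodes[i]); to <- c(to, g$nodes[j])
      mark <- c(mark, if (m == MARK_UNDIR) "undirected" else "bidirected")
    }
  }
  data.frame(from = from, to = to, mark = mark, stringsAsFactors = FALSE)
}

#' Number of edges in a mixed graph
#' @param g a `mixed_graph`.
#' @export
n_edges <- function(g) nrow(graph_edges(g))

#' Validate the internal consistency of a mixed graph
#'
#' Checks that the mark table uses legal codes, symmetric marks are stored
#' symmetrically, no self edges exist, and no arrow points into a variant.
#' @param g a `mixed_graph`.
#' @return `g`, invisibly; stops on violation.
#' @export
validate_graph <- function(g) {
  m <- g$marks
  stopifnot(is.matrix(m), nrow(m) == ncol(m), all(m %in% 0:3),
            all(diag(m) == MARK_ABSENT))
  p <- nrow(m)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i >= j) next
    a <- m[i, j]; b <- m[j, i]
    ok <- (a == b && a %in% c(MARK_ABSENT, MARK_UNDIR, MARK_BIDIR)) ||
      (a == MARK_DIR && b == MARK_ABSENT) || (b == MARK_DIR && a == MARK_ABSENT)
    if (!ok) stop("inconsistent marks between ", g$nodes[i], " and ", g$nodes[j])
  }
  into_variant <- which(m == MARK_DIR, arr.ind = TRUE)
  if (length(into_variant) &&
      any(g$roles[into_variant[, 2]] == "variant"))
    stop("graph has an arrow pointing into a variant node")
  invisible(g)
}

#' Test whether a mixed graph is acyclic under every orientation
#'
#' Undirected/bidirected edges are checked by exhausting both orientations
#' when there are at most `exhaustive_limit` of them, otherwise each such
#' edge is contracted conservatively (a cycle through the directed part alone
#' is still detected).
#'
#' @param g a `mixed_graph`.
#' @param exhaustive_limit maximum number of undirected edges to orient
#'   exhaustively.
#' @return logical.
#' @export
is_acyclic <- function(g, exhaustive_limit = 3L) {
  ed <- graph_edges(g)
  und <- ed[ed$mark != "directed", , drop = FALSE]
  dir_ <- ed[ed$mark == "directed", , drop = FALSE]
  k <- nrow(und)
  dag_ok <- function(edges_df) {
    # Kahn's algorithm on node names
    nodes <- g$nodes
    indeg <- stats::setNames(integer(length(nodes)), nodes)
    if (nrow(edges_df)) {
      tab <- table(edges_df$to)
      indeg[names(tab)] <- as.integer(tab)
    }
    remaining <- edges_df
    queue <- nodes[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
      out <- remaining$from == v
      for (w in remaining$to[out]) {
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) queue <- c(queue, w)
      }
      remaining <- remaining[!out, , drop = FALSE]
    }
    seen == length(nodes)
  }
  if (k == 0L) return(dag_ok(dir_))
  if (k <= exhaustive_limit) {
    for (bits in 0:(2^k - 1L)) {
      flip <- as.logical(bitwAnd(bits, 2L^(seq_len(k) - 1L)))
      oriented <- und
      oriented$from <- ifelse(flip, und$to, und$from)
      oriented$to <- ifelse(flip, und$from, und$to)
      if (!dag_ok(rbind(dir_[, 1:2], oriented[, 1:2],
                        make.row.names = FALSE)))
        return(FALSE)
    }
    return(TRUE)
  }
  # many undirected edges: require the directed part alone to be acyclic
  dag_ok(dir_)
}

#' Compare two mixed graphs
#'
#' @param a,b `mixed_graph` objects over the same node set (any node order).
#' @param normalize_marks treat undirected and bidirected as the same mark
#'   (both state "edge present, direction undetermined").
#' @return logical.
#' @export
graph_equal <- function(a, b, normalize_marks = TRUE) {
  if (!setequal(a$nodes, b$nodes)) return(FALSE)
  ma <- a$marks
  mb <- b$marks[a$nodes, a$nodes]
  if (normalize_marks) {
    ma[ma == MARK_BIDIR] <- MARK_UNDIR
    mb[mb == MARK_BIDIR] <- MARK_UNDIR
  }
  identical(unname(ma), unname(mb))
}

#' Relabel / reorder the nodes of a mixed graph
#'
#' @param g a `mixed_graph`.
#' @param order character vector: the new node order (a permutation of
#'   `g$nodes`).
#' @return a `mixed_graph` with rows/columns permuted accordingly.
#' @export
reorder_nodes <- function(g, order) {
  stopifnot(setequal(order, g$nodes))
  idx <- match(order, g$nodes)
  g$nodes <- g$nodes[idx]
  g$roles <- g$roles[idx]
  g$marks <- g$marks[idx, idx]
  g
}

#' Convert a mixed graph to an adjacency matrix
#'
#' Parents are in rows and children in columns: a directed edge i -> j sets
#' `A[i, j] = 1`; undirected and bidirected edges set both `A[i, j]` and
#' `A[j, i]` to 1.
#'
#' @param g a `mixed_graph`.
#' @return a 0/1 integer matrix with node names as dimnames.
#' @export
as_adjacency <- function(g) {
  m <- g$marks
  a <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  a[m == MARK_DIR] <- 1L
  sym <- m == MARK_UNDIR | m == MARK_BIDIR
  a[sym] <- 1L
  a
}

#' Build a mixed graph from an adjacency matrix
#'
#' Inverse of [as_adjacency()]: `A[i, j] = A[j, i] = 1` becomes an undirected
#' edge, `A[i, j] = 1` alone a directed edge i -> j (parents in rows,
#' children in columns).
#'
#' @param a square 0/1 matrix with identical row and column names.
#' @param n_gv number of leading variant nodes.
#' @return a `mixed_graph`.
#' @export
graph_from_adjacency <- function(a, n_gv = 0L) {
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  nodes <- rownames(a)
  if (is.null(nodes)) nodes <- paste0("X", seq_len(nrow(a)))
  g <- mixed_graph(nodes, n_gv)
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (i >= j) next
    if (a[i, j] != 0 && a[j, i] != 0) g <- set_edge(g, i, j, "undirected")
    else if (a[i, j] != 0) g <- set_edge(g, i, j, "directed")
    else if (a[j, i] != 0) g <- set_edge(g, j, i, "directed")
  }
  g
}

#' Write / read a tab-separated edge list
#'
#' Format: one edge per line, `from<TAB>to<TAB>mark` with mark one of
#' `-->` (directed), `---` (undirected), `<->` (bidirected). A header line
#' `# nodes: ...` and `# n_gv: ...` preserves isolated nodes and roles.
#'
#' @param g a `mixed_graph`.
#' @param path file path.
#' @export
write_edge_list <- function(g, path) {
  ed <- graph_edges(g)
  sym <- c(directed = "-->", undirected = "---", bidirected = "<->")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste("# nodes:", paste(g$nodes, collapse = " ")),
               paste("# n_gv:", sum(g$roles == "variant"))), con)
  if (nrow(ed))
    writeLines(paste(ed$from, ed$to, sym[ed$mark], sep = "\t"), con)
  invisible(path)
}

#' @rdname write_edge_list
#' @return `read_edge_list` returns a `mixed_graph`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, value = TRUE, invert = TRUE)
  body <- body[nzchar(body)]
  nodes_line <- sub("^# nodes: *", "", grep("^# nodes:", hdr, value = TRUE))
  ngv_line <- sub("^# n_gv: *", "", grep("^# n_gv:", hdr, value = TRUE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (length(nodes_line)) {
    nodes <- strsplit(nodes_line, " +")[[1]]
    n_gv <- as.integer(ngv_line)
  } else {
    nodes <- unique(unlist(lapply(parts, `[`, 1:2)))
    n_gv <- 0L
  }
  g <- mixed_graph(nodes, n_gv)
  for (pr in parts) {
    type <- switch(pr[3], "-->" = "directed", "---" = "undirected",
                   "<->" = "bidirected",
                   stop("unknown edge mark: ", pr[3]))
    g <- set_edge(g, pr[1], pr[2], type)
  }
  g
}

#' @export
print.mixed_graph <- function(x, ...) {
  nv <- sum(x$roles == "variant")
  cat("Mixed graph:", length(x$nodes), "nodes (", nv, "variant,",
      length(x$nodes) - nv, "phenotype ),", n_edges(x), "edges\n")
  ed <- graph_edges(x)
  if (nrow(ed)) {
    sym <- c(directed = "-->", undirected = "---", bidirected = "<->")
    cat(paste0("  ", ed$from, " ", sym[ed$mark], " ", ed$to, collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Plot a mixed graph
#'
#' Renders via the igraph package when available; undirected and bidirected
#' edges are drawn without arrowheads, variants as squares.
#'
#' @param x a `mixed_graph`.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.mixed_graph <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting requires the igraph package")
  ed <- graph_edges(x)
  ig <- igraph::graph_from_data_frame(
    ed[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = x$nodes))
  shapes <- ifelse(x$roles == "variant", "square", "circle")
  arrow <- ifelse(ed$mark == "directed", 2, 0)
  igraph::plot.igraph(ig, vertex.shape = shapes, edge.arrow.mode = arrow, ...)
  invisible(x)
}
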