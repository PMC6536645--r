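# The two-step learner: Step I infers an undirected skeleton with
# LOND-controlled (conditional) independence tests; Step II orients edges
# using the principle of Mendelian randomization: first variant edges, then
# v-structures, then remaining edges by matching node triples against the
# five basic models.

# ---------------------------------------------------------------- Step I --

# Core skeleton loop on an existing engine. Stable-PC style: within each
# conditioning-set size, candidate neighbourhoods are frozen at the start of
# the level and edge removals are applied at the end, which damps the
# dependence of the result on the node ordering.
skeleton_core <- function(eng, roles, max_cond) {
  p <- length(eng$nodes)
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepsets <- new.env(parent = emptyenv())
  l <- 0L
  repeat {
    nbrs <- lapply(seq_len(p), function(i) which(adj[i, ]))
    pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    any_testable <- FALSE
    removals <- list()
    for (k in seq_len(nrow(pairs))) {
      x <- pairs[k, 1]; y <- pairs[k, 2]
      cands <- list(setdiff(nbrs[[x]], y), setdiff(nbrs[[y]], x))
      tested <- character(0)
      removed <- FALSE
      for (side in 1:2) {
        pool <- cands[[side]]
        if (length(pool) < l) next
        any_testable <- TRUE
        sets <- if (l == 0L) list(integer(0)) else
          lapply(asplit(utils::combn(seq_along(pool), l), 2L),
                 function(ix) pool[ix])
        for (S in sets) {
          key <- paste(S, collapse = ",")
          if (key %in% tested) next
          tested <- c(tested, key)
          rec <- engine_test(eng, x, y, S)
          if (is.null(rec)) next  # uninformative: keep edge
          if (!rec$rejected) {    # independence accepted: drop the edge
            removals[[length(removals) + 1L]] <- c(x, y)
            sepset_set(sepsets, x, y, S)
            removed <- TRUE
            break
          }
        }
        if (removed) break
      }
    }
    for (rm_ in removals) adj[rm_[1], rm_[2]] <- adj[rm_[2], rm_[1]] <- FALSE
    l <- l + 1L
    if (l > max_cond || !any_testable || !any(adj)) break
  }
  g <- mixed_graph(eng$nodes, sum(roles == "variant"))
  for (i in seq_len(p)) for (j in seq_len(p))
    if (i < j && adj[i, j]) g <- set_edge(g, i, j, "undirected")
  list(graph = g, sepsets = sepsets)
}

#' Learn the graph skeleton with LOND-controlled independence tests
#'
#' Starts from the fully connected undirected graph and removes the edge
#' between two nodes whenever some marginal or conditional independence test
#' accepts the null at the significance level the LOND stream assigns to
#' that test. Conditioning sets are drawn from current neighbourhoods in
#' increasing size; the test schedule is deterministic (node pairs in
#' canonical order, conditioning sets by size then lexicographically) and
#' removals are applied level-wise.
#'
#' @param corr correlation matrix with row/column names.
#' @param n sample size behind `corr`.
#' @param roles factor/character of `"variant"` / `"phenotype"` per column
#'   of `corr` (variants first).
#' @param lond a [lond_state()]; the advanced state is returned.
#' @param max_cond largest conditioning-set size; default
#'   `min(ncol(corr) - 2, 4)`.
#' @return list with `graph` (undirected `mixed_graph`), `sepsets` (named
#'   list: for each removed pair, the conditioning set that separated it),
#'   `tests` (data-frame log of every test performed) and `lond` (final
#'   controller state).
#' @export
learn_skeleton <- function(corr, n, roles, lond = lond_state(),
                           max_cond = NULL) {
  nodes <- colnames(corr)
  if (is.null(nodes)) nodes <- paste0("X", seq_len(ncol(corr)))
  if (is.null(max_cond)) max_cond <- max(0L, min(ncol(corr) - 2L, 4L))
  eng <- new_ci_engine(nodes, corr, n, lond)
  sk <- skeleton_core(eng, roles, max_cond)
  list(graph = sk$graph, sepsets = sepsets_as_list(sk$sepsets, nodes),
       tests = engine_log(eng), lond = eng$lond)
}

# --------------------------------------------------------------- Step II --

#' Orient edges that involve a genetic variant
#'
#' Under Mendelian randomization, genotype causes phenotype; every
#' variant--phenotype edge in the skeleton is therefore directed from the
#' variant to the phenotype. Variant--variant edges (possible under linkage)
#' are left undirected; nothing else changes.
#'
#' @param graph a `mixed_graph` (typically the skeleton from
#'   [learn_skeleton()]).
#' @return the partially oriented graph.
#' @export
orient_variant_edges <- function(graph) {
  p <- length(graph$nodes)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    if (graph$roles[i] == "variant" && graph$roles[j] == "phenotype" &&
        edge_mark(graph, i, j) == "undirected")
      graph <- set_edge(graph, i, j, "directed")
  }
  graph
}

# Shared v-structure pass over an engine (may run new tests via the same
# LOND stream). Orients X -> Y <- Z for unshielded triples whose middle node
# was not in the separating set and whose endpoints are conditionally
# dependent given the middle node.
v_structure_core <- function(eng, graph, sepsets) {
  p <- length(graph$nodes)
  adj <- adjacency_any(graph)
  for (y in seq_len(p)) {
    if (graph$roles[y] == "variant") next  # no arrowheads into variants
    nb <- which(adj[y, ])
    if (length(nb) < 2L) next
    for (xi in seq_along(nb)) for (zi in seq_along(nb)) {
      if (xi >= zi) next
      x <- nb[xi]; z <- nb[zi]
      if (adj[x, z]) next  # shielded
      rec <- engine_test(eng, x, z, y)
      if (is.null(rec) || !rec$rejected) next  # need dependence given y
      ss <- sepset_get(sepsets, x, z)
      if (!is.null(ss) && y %in% ss) next
      if (edge_mark(graph, x, y) == "undirected")
        graph <- set_edge(graph, x, y, "directed")
      if (edge_mark(graph, z, y) == "undirected")
        graph <- set_edge(graph, z, y, "directed")
    }
  }
  graph
}

#' Orient v-structures
#'
#' For every unshielded triple X--Y--Z (X and Z nonadjacent), tests X
#' against Z given Y — reusing the cached decision when the skeleton step
#' already ran that test, otherwise running it through the same LOND stream
#' — and orients X -> Y <- Z when X and Z are conditionally dependent given
#' Y and Y was not in their separating set. Existing variant -> phenotype
#' arrows are never reversed, and no arrowhead is ever created at a variant.
#'
#' @param graph partially oriented `mixed_graph` (variant edges oriented).
#' @param sepsets named separating-set list from [learn_skeleton()].
#' @param corr,n correlation matrix and sample size (for the extra tests).
#' @param lond the LOND state carried over from the skeleton step.
#' @param tests optional test log from [learn_skeleton()], used to reuse
#'   decisions instead of re-running (and re-counting) tests.
#' @return list with the updated `graph`, extended `tests` log and `lond`
#'   state.
#' @export
orient_v_structures <- function(graph, sepsets, corr, n,
                                lond = lond_state(), tests = NULL) {
  eng <- rebuild_engine(graph$nodes, corr, n, lond, tests)
  ss <- sepsets_from_list(sepsets, graph$nodes)
  graph <- v_structure_core(eng, graph, ss)
  list(graph = graph, tests = engine_log(eng), lond = eng$lond)
}

# Rehydrate an engine (cache + stream position) from a test log.
rebuild_engine <- function(nodes, corr, n, lond, tests) {
  eng <- new_ci_engine(nodes, corr, n, lond)
  if (!is.null(tests) && nrow(tests)) {
    for (k in seq_len(nrow(tests))) {
      x <- match(tests$x[k], nodes); y <- match(tests$y[k], nodes)
      S <- if (nzchar(tests$S[k]))
        match(strsplit(tests$S[k], ",", fixed = TRUE)[[1]], nodes)
      else integer(0)
      rec <- list(x = x, y = y, S = S, r = tests$r[k],
                  statistic = tests$statistic[k], p = tests$p_value[k],
                  alpha = tests$alpha[k], rejected = tests$rejected[k],
                  index = tests$index[k])
      eng$cache[[test_key(x, y, S)]] <- rec
      eng$n_records <- eng$n_records + 1L
      if (eng$n_records > length(eng$records))
        eng$records <- c(eng$records, vector("list", length(eng$records)))
      eng$records[[eng$n_records]] <- rec
    }
  }
  eng
}

sepsets_from_list <- function(sepsets, nodes) {
  env <- new.env(parent = emptyenv())
  for (nm in names(sepsets)) {
    ij <- match(strsplit(nm, ",", fixed = TRUE)[[1]], nodes)
    S <- match(sepsets[[nm]], nodes)
    if (length(sepsets[[nm]]) == 0L) S <- integer(0)
    sepset_set(env, ij[1], ij[2], S)
  }
  env
}

# Classify the triple (A, B, C) — A the variant-analog with A -> B already
# directed, B -- C the single undirected edge — against the five basic
# models, using only decisions already in the test cache/sepsets.
# Returns "B->C" (canonical-chain analog), "C->B" (collider analog) or
# "leave" (common-cause-plus-dependence analog, or no unique match).
classify_triple <- function(eng, graph, sepsets, a, b, c) {
  m_ac <- edge_mark(graph, a, c)
  if (m_ac == "forward") return("leave")           # A -> C present: M4-like
  if (m_ac != "absent") return("none")             # not a qualifying triple
  rec <- engine_lookup(eng, a, c, b)
  ss <- sepset_get(sepsets, a, c)
  cond_indep <- if (!is.null(rec)) !rec$rejected
                else if (!is.null(ss)) b %in% ss
                else NA
  if (is.na(cond_indep)) return("leave")
  if (cond_indep) return("B->C")                   # M1 analog
  marg <- engine_lookup(eng, a, c, integer(0))
  marg_indep <- if (!is.null(marg)) !marg$rejected
                else (!is.null(ss) && length(ss) == 0L)
  if (marg_indep) return("C->B")                   # M2 analog
  "leave"
}

#' Match a node triple against the five basic models
#'
#' For a triple `(A, B, C)` in which `A -> B` is already directed and
#' `B -- C` is the only undirected edge, compares the observed dependence
#' pattern (recorded marginal tests, the conditional test of A and C given
#' B, and the separating sets) to the signatures of the five basic models,
#' with A playing the variant-analog role. A unique match with the
#' canonical-chain model orients `B -> C`; a unique match with the collider
#' model orients `C -> B`; the common-cause-plus-dependence pattern, or the
#' absence of a unique match, leaves the edge bidirected.
#'
#' @param graph the current partially oriented `mixed_graph`.
#' @param triple character vector `c(A, B, C)` of node names.
#' @param tests test log (as returned in `$tests` by the learner steps).
#' @param sepsets named separating-set list.
#' @return one of `"B->C"`, `"C->B"`, `"leave"` (leave bidirected) or
#'   `"none"` (the triple does not satisfy the preconditions).
#' @export
match_pmr_model <- function(graph, triple, tests, sepsets) {
  idx <- node_index(graph, triple)
  if (edge_mark(graph, idx[1], idx[2]) != "forward" ||
      edge_mark(graph, idx[2], idx[3]) != "undirected")
    return("none")
  eng <- rebuild_engine(graph$nodes, corr = NULL, n = NULL,
                        lond = lond_state(), tests = tests)
  ss <- sepsets_from_list(sepsets, graph$nodes)
  classify_triple(eng, graph, ss, idx[1], idx[2], idx[3])
}

# Step II (5): iterate over undirected phenotype--phenotype edges, gather
# the model-match decisions from every qualifying triple (triples containing
# a variant first, then canonical order) and apply a unique orientation;
# conflicting orientations or pure common-cause matches set the edge
# bidirected. Re-scans until a full pass changes nothing.
orient_remaining_core <- function(eng, graph, sepsets) {
  p <- length(graph$nodes)
  repeat {
    changed <- FALSE
    for (b in seq_len(p)) for (cc in seq_len(p)) {
      if (b >= cc) next
      if (edge_mark(graph, b, cc) != "undirected") next
      adj <- adjacency_any(graph)
      cand <- setdiff(which(adj[b, ] | adj[cc, ]), c(b, cc))
      cand <- cand[order(graph$roles[cand] != "variant", cand)]
      decisions <- character(0)
      for (a in cand) {
        if (edge_mark(graph, a, b) == "forward")
          d <- classify_triple(eng, graph, sepsets, a, b, cc)
        else if (edge_mark(graph, a, cc) == "forward") {
          d <- classify_triple(eng, graph, sepsets, a, cc, b)
          d <- switch(d, "B->C" = "C->B", "C->B" = "B->C", d)
        } else next
        if (d != "none") decisions <- c(decisions, d)
      }
      orient <- setdiff(unique(decisions), "leave")
      if (length(orient) == 1L) {
        graph <- if (orient == "B->C") set_edge(graph, b, cc, "directed")
                 else set_edge(graph, cc, b, "directed")
        changed <- TRUE
      } else if (length(orient) > 1L || "leave" %in% decisions) {
        graph <- set_edge(graph, b, cc, "bidirected")
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  graph
}

# ------------------------------------------------------------- pipeline --

#' Learn a causal network with Mendelian randomization anchoring
#'
#' The main fitting function. Runs the full pipeline on an individuals x
#' variables data matrix whose first `n_gv` columns are genotypes coded
#' 0/1/2 and remaining columns molecular phenotypes: (robust) correlation,
#' LOND-controlled skeleton learning, a-priori orientation of variant
#' edges, v-structure orientation with extra conditional tests through the
#' same LOND stream, and iterative matching of the remaining undirected
#' edges against the five basic models. The result is deterministic given
#' the input and column order.
#'
#' @param data numeric matrix or data frame, samples in rows, genotype
#'   columns first; mutually exclusive with `corr`/`n`. Missing values are
#'   rejected (impute beforehand, or supply `corr` and `n` instead).
#' @param n_gv number of leading genotype (variant) columns; 0 degrades to
#'   variant-free constraint-based learning among phenotypes.
#' @param corr optionally, a precomputed correlation matrix.
#' @param n sample size; required with `corr`.
#' @param fdr overall FDR target for the LOND stream.
#' @param a LOND exponent (integer > 1).
#' @param beta robustness parameter of [robust_correlation()]; 0 is Pearson
#'   correlation, 0.005 the conventional choice under suspected outliers.
#' @param max_cond largest conditioning-set size (default
#'   `min(p - 2, 4)` for p variables).
#' @param tester advanced hook: a function `(x, y, S) ->
#'   list(r, statistic, p)` (indices into the node set) replacing the
#'   correlation-based test, e.g. to drive the learner with scripted
#'   decisions. With a `tester`, supply `nodes` instead of data.
#' @param nodes node names (only needed with `tester`).
#' @return an object of class `mrpc`: list with `graph` (the inferred
#'   `mixed_graph`), `tests` (log of all independence tests in stream
#'   order), `sepsets`, `lond` (final controller state), `params` and
#'   `call`.
#' @examples
#' topo <- canned_topology("M1")
#' d <- simulate_dataset(topo, n = 500, seed = 1)
#' fit <- mrpc(d, n_gv = 1)
#' fit$graph
#' @export
mrpc <- function(data = NULL, n_gv = 0L, corr = NULL, n = NULL,
                 fdr = 0.05, a = 2L, beta = 0, max_cond = NULL,
                 tester = NULL, nodes = NULL) {
  cl <- match.call()
  if (!is.null(data)) {
    x <- as.matrix(data)
    if (!is.numeric(x)) stop("data must be numeric")
    if (is.null(colnames(x)))
      colnames(x) <- c(paste0("V", seq_len(n_gv)),
                       paste0("T", seq_len(ncol(x) - n_gv)))
    corr <- robust_correlation(x, beta = beta)
    n <- nrow(x)
    nodes <- colnames(x)
  } else if (!is.null(corr)) {
    if (is.null(n)) stop("sample size n is required with a correlation matrix")
    nodes <- colnames(corr)
    if (is.null(nodes)) nodes <- c(paste0("V", seq_len(n_gv)),
                                   paste0("T", seq_len(ncol(corr) - n_gv)))
    dimnames(corr) <- list(nodes, nodes)
  } else if (is.null(tester)) {
    stop("supply data, or corr with n, or a tester with nodes")
  }
  if (is.null(nodes)) stop("nodes are required with a tester")
  p <- length(nodes)
  if (n_gv < 0L || n_gv > p) stop("invalid n_gv")
  if (!is.null(n) && n <= 4) stop("sample size must exceed 4")
  roles <- rep(c("variant", "phenotype"), c(n_gv, p - n_gv))
  if (is.null(max_cond)) max_cond <- max(0L, min(p - 2L, 4L))
  lond <- lond_state(fdr, a)
  eng <- new_ci_engine(nodes, corr, n, lond, tester)
  sk <- skeleton_core(eng, roles, max_cond)
  g <- orient_variant_edges(sk$graph)
  g <- v_structure_core(eng, g, sk$sepsets)
  g <- orient_remaining_core(eng, g, sk$sepsets)
  validate_graph(g)
  structure(list(graph = g,
                 tests = engine_log(eng),
                 sepsets = sepsets_as_list(sk$sepsets, nodes),
                 lond = eng$lond,
                 params = list(n_gv = n_gv, fdr = fdr, a = a, beta = beta,
                               max_cond = max_cond, n = n),
                 call = cl),
            class = "mrpc")
}

#' @export
print.mrpc <- function(x, ...) {
  cat("Causal network learned by Mendelian-randomization-anchored PC\n")
  print(x$graph)
  cat(sprintf("%d independence tests, %d rejections (FDR target %g, a = %d, beta = %g)\n",
              x$lond$i, x$lond$D, x$params$fdr, x$params$a, x$params$beta))
  invisible(x)
}

#' @export
summary.mrpc <- function(object, ...) {
  ed <- graph_edges(object$graph)
  out <- list(
    n_nodes = length(object$graph$nodes),
    n_variants = sum(object$graph$roles == "variant"),
    edges = ed,
    n_tests = object$lond$i,
    n_rejections = object$lond$D,
    final_alpha = lond_next_alpha(object$lond),
    params = object$params)
  class(out) <- "summary.mrpc"
  out
}

#' @export
print.summary.mrpc <- function(x, ...) {
  cat(sprintf("Nodes: %d (%d variants); edges: %d\n",
              x$n_nodes, x$n_variants, nrow(x$edges)))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  cat(sprintf("Tests: %d, rejections: %d; next LOND alpha would be %.4g\n",
              x$n_tests, x$n_rejections, x$final_alpha))
  cat(sprintf("Parameters: fdr = %g, a = %d, beta = %g, max_cond = %d\n",
              x$params$fdr, x$params$a, x$params$beta, x$params$max_cond))
  invisible(x)
}

#' @export
plot.mrpc <- function(x, ...) plot(x$graph, ...)
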