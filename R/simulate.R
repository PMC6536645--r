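# Linear-Gaussian genotype/phenotype simulator. Genotypes are biallelic
# Hardy-Weinberg draws over {0, 1, 2}; each phenotype is normal around a
# linear combination of its parents. Undirected edges are treated as a 50:50
# per-sample mixture of the two orientations.

#' Simulate biallelic genotypes under Hardy-Weinberg equilibrium
#'
#' @param n number of individuals.
#' @param q minor allele frequency in `[0, 1]`.
#' @param seed optional integer seed (local to this call).
#' @return integer vector over `{0, 1, 2}` with probabilities
#'   `(1-q)^2, 2q(1-q), q^2`.
#' @export
simulate_genotype <- function(n, q = 0.45, seed = NULL) {
  stopifnot(q >= 0, q <= 1, n >= 1)
  if (!is.null(seed)) { old <- save_rng(); on.exit(restore_rng(old)); set.seed(seed) }
  sample(0:2, n, replace = TRUE, prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
}

save_rng <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}
restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}

# topological order of the directed part of a topology graph
topo_order <- function(g) {
  p <- length(g$nodes)
  dir_ <- g$marks == MARK_DIR
  indeg <- colSums(dir_)
  order_ <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    v <- avail[1]; avail <- avail[-1]
    order_ <- c(order_, v)
    ch <- which(dir_[v, ])
    indeg[ch] <- indeg[ch] - 1L
    avail <- sort(c(avail, ch[indeg[ch] == 0L & !(ch %in% order_)]))
  }
  if (length(order_) != p) stop("directed part of the graph is cyclic")
  order_
}

# Generate one dataset under a fully directed orientation of the topology.
generate_directed <- function(topo, oriented, n, coefs) {
  g <- oriented
  nodes <- g$nodes
  p <- length(nodes)
  x <- matrix(0, n, p, dimnames = list(NULL, nodes))
  vidx <- which(g$roles == "variant")
  sig <- rep(0, p)
  sig[g$roles == "phenotype"] <- topo$sigma
  for (j in topo_order(g)) {
    if (j %in% vidx) {
      x[, j] <- simulate_genotype(n, topo$q[match(j, vidx)])
    } else {
      parents <- which(g$marks[, j] == MARK_DIR)
      mu <- rep(topo$gamma0, n)
      for (pa in parents) mu <- mu + coefs[[paste(pa, j)]] * x[, pa]
      x[, j] <- stats::rnorm(n, mu, sig[j])
    }
  }
  x
}

#' Simulate a genotype + phenotype data matrix from a topology
#'
#' Nodes are generated in topological order: variants as Hardy-Weinberg
#' genotype draws, each phenotype as
#' `N(gamma0 + sum(gamma_k * parent_k), sigma^2)`. Every undirected or
#' bidirected edge is handled by generating the data under both
#' orientations and keeping, per sample, one version with probability 1/2
#' each. With `heterogeneous = TRUE` each edge coefficient is drawn
#' uniformly from `{0.2, 0.5, 1.0}` (once per call) instead of using the
#' topology's stored coefficients.
#'
#' @param topology a [topology_spec()].
#' @param n sample size.
#' @param gamma optional scalar overriding every stored edge coefficient.
#' @param heterogeneous draw each coefficient from `{0.2, 0.5, 1.0}`.
#' @param seed optional integer seed making the draw fully reproducible.
#' @return numeric matrix, samples x variables, variants in the leading
#'   columns; the realized per-edge coefficients are attached as attribute
#'   `"coefficients"`.
#' @examples
#' d <- simulate_dataset(canned_topology("M1"), n = 100, seed = 1)
#' @export
simulate_dataset <- function(topology, n, gamma = NULL,
                             heterogeneous = FALSE, seed = NULL) {
  stopifnot(inherits(topology, "topology_spec"), n >= 1)
  if (!is.null(seed)) { old <- save_rng(); on.exit(restore_rng(old)); set.seed(seed) }
  g <- topology$graph
  ed <- graph_edges(g)
  gam <- topology$coefficients
  if (!is.null(gamma)) gam[] <- gamma
  if (heterogeneous)
    gam[] <- sample(c(0.2, 0.5, 1.0), length(gam), replace = TRUE)
  und <- which(ed$mark != "directed")
  k <- length(und)
  # coefficient lookup keyed "parent_index child_index" for a given orientation
  coef_map <- function(oriented_ed) {
    keys <- paste(match(oriented_ed$from, g$nodes),
                  match(oriented_ed$to, g$nodes))
    stats::setNames(as.list(gam), keys)
  }
  if (k == 0L) {
    x <- generate_directed(topology, g, n, coef_map(ed))
  } else {
    if (k > 8L) stop("too many undirected edges to mix over (", k, ")")
    assign_ <- matrix(stats::runif(n * k) < 0.5, n, k)
    x <- NULL
    for (bits in 0:(2^k - 1L)) {
      flip <- as.logical(bitwAnd(bits, 2L^(seq_len(k) - 1L)))
      oriented <- g
      oed <- ed
      for (e in seq_len(k)) {
        i <- und[e]
        from <- if (flip[e]) ed$to[i] else ed$from[i]
        to <- if (flip[e]) ed$from[i] else ed$to[i]
        oriented <- set_edge(oriented, from, to, "directed")
        oed$from[i] <- from; oed$to[i] <- to; oed$mark[i] <- "directed"
      }
      if (!is_acyclic(oriented))
        stop("an orientation of the undirected edges creates a cycle")
      xv <- generate_directed(topology, oriented, n, coef_map(oed))
      rows <- rowSums(assign_ == matrix(flip, n, k, byrow = TRUE)) == k
      if (is.null(x)) x <- xv else x[rows, ] <- xv[rows, ]
    }
  }
  attr(x, "coefficients") <- gam
  x
}

#' @rdname simulate_dataset
#' @param object a `topology_spec` (S3 `simulate` method).
#' @param nsim number of datasets.
#' @param ... passed on to `simulate_dataset`.
#' @return `simulate()` returns a list of `nsim` data matrices.
#' @export
simulate.topology_spec <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) { old <- save_rng(); on.exit(restore_rng(old)); set.seed(seed) }
  lapply(seq_len(nsim), function(i) simulate_dataset(object, ...))
}

#' Replace random phenotype cells with uniform outliers
#'
#' Emulates gross contamination: `k` uniformly chosen phenotype cells
#' (genotype cells are never touched) are replaced by draws from
#' `U(range[1], range[2])`.
#'
#' @param data samples x variables matrix.
#' @param n_gv number of leading genotype columns (excluded from injection).
#' @param k number of cells to replace.
#' @param range support of the uniform replacement values.
#' @param seed optional integer seed.
#' @return list with `data` (modified copy) and `cells` (data frame of
#'   `row`, `col` indices of the replaced cells).
#' @export
inject_outliers <- function(data, n_gv = 0L, k = 10L, range = c(-10, 10),
                            seed = NULL) {
  x <- as.matrix(data)
  if (!is.null(seed)) { old <- save_rng(); on.exit(restore_rng(old)); set.seed(seed) }
  ph_cols <- setdiff(seq_len(ncol(x)), seq_len(n_gv))
  n_cells <- nrow(x) * length(ph_cols)
  stopifnot(k >= 0, k <= n_cells)
  if (k == 0L) return(list(data = x, cells = data.frame(row = integer(0),
                                                        col = integer(0))))
  pick <- sample.int(n_cells, k)
  row <- (pick - 1L) %% nrow(x) + 1L
  col <- ph_cols[(pick - 1L) %/% nrow(x) + 1L]
  x[cbind(row, col)] <- stats::runif(k, range[1], range[2])
  list(data = x, cells = data.frame(row = row, col = col))
}

#' Shuffle the phenotype columns of a data matrix
#'
#' Order-sensitivity probe: returns a copy with the phenotype columns
#' permuted (genotype columns stay in place) together with the permutation
#' used, so a learner's output can be mapped back and compared.
#'
#' @param data samples x variables matrix.
#' @param n_gv number of leading genotype columns.
#' @param seed optional integer seed.
#' @return list with `data` and `perm` (the new column order, a permutation
#'   of `seq_len(ncol(data))` fixing the first `n_gv` entries).
#' @export
shuffle_phenotypes <- function(data, n_gv = 0L, seed = NULL) {
  x <- as.matrix(data)
  if (!is.null(seed)) { old <- save_rng(); on.exit(restore_rng(old)); set.seed(seed) }
  ph <- setdiff(seq_len(ncol(x)), seq_len(n_gv))
  perm <- c(seq_len(n_gv), sample(ph))
  list(data = x[, perm, drop = FALSE], perm = perm)
}

#' The standard signal-strength x sample-size simulation grid
#'
#' @return data frame of the 12 cells: `gamma` in `{0.2, 0.5, 1.0}` crossed
#'   with `n` in `{50, 200, 500, 1000}`.
#' @export
simulation_grid <- function() {
  expand.grid(gamma = c(0.2, 0.5, 1.0), n = c(50L, 200L, 500L, 1000L),
              KEEP.OUT.ATTRS = FALSE)
}
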