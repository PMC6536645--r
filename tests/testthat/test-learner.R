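test_that("skeleton stays empty under mutual independence", {
  ok <- 0L
  for (r in 1:200) {
    set.seed(300 + r)
    d <- matrix(rnorm(3000), 1000, 3,
                dimnames = list(NULL, c("T1", "T2", "T3")))
    sk <- learn_skeleton(cor(d), n = 1000, roles = rep("phenotype", 3))
    if (n_edges(sk$graph) == 0L) ok <- ok + 1L
  }
  expect_gte(ok / 200, 0.95)
})

test_that("skeleton recovers the chain and separates variant from target", {
  ok <- 0L
  for (r in 1:100) {
    d <- simulate_dataset(canned_topology("M1", gamma = 1), n = 1000,
                          seed = 400 + r)
    sk <- learn_skeleton(cor(d), n = 1000,
                         roles = c("variant", "phenotype", "phenotype"))
    good <- has_edge(sk$graph, "V1", "T1") &&
      has_edge(sk$graph, "T1", "T2") &&
      !has_edge(sk$graph, "V1", "T2") &&
      identical(sk$sepsets[["V1,T2"]], "T1")
    if (good) ok <- ok + 1L
  }
  expect_gte(ok / 100, 0.95)
})

test_that("a perfectly duplicated phenotype keeps its edge", {
  set.seed(9)
  t1 <- rnorm(200)
  d <- cbind(T1 = t1, T2 = t1)
  co <- suppressWarnings(cor(d))
  sk <- learn_skeleton(co, n = 200, roles = rep("phenotype", 2))
  expect_true(has_edge(sk$graph, "T1", "T2"))
})

test_that("variant edges are oriented away from the variant, only", {
  g <- mixed_graph(c("V1", "T1", "T2"), 1)
  g <- set_edge(g, "V1", "T1", "undirected")
  g <- set_edge(g, "T1", "T2", "undirected")
  o <- orient_variant_edges(g)
  expect_equal(edge_mark(o, "V1", "T1"), "forward")
  expect_equal(edge_mark(o, "T1", "T2"), "undirected")
  # applied once per variant edge; no variant-free change
  g2 <- mixed_graph(c("T1", "T2"), 0)
  g2 <- set_edge(g2, "T1", "T2", "undirected")
  expect_true(graph_equal(orient_variant_edges(g2), g2))
})

test_that("collider data yields a v-structure, chain data does not", {
  v_ok <- 0L; chain_ok <- 0L
  for (r in 1:100) {
    d2 <- simulate_dataset(canned_topology("M2", gamma = 1), n = 1000,
                           seed = 500 + r)
    f2 <- mrpc(d2, n_gv = 1)
    if (edge_mark(f2$graph, "T2", "T1") == "forward") v_ok <- v_ok + 1L
    d1 <- simulate_dataset(canned_topology("M1", gamma = 1), n = 1000,
                           seed = 600 + r)
    f1 <- mrpc(d1, n_gv = 1)
    if (edge_mark(f1$graph, "T1", "T2") == "forward" &&
        edge_mark(f1$graph, "V1", "T1") == "forward")
      chain_ok <- chain_ok + 1L
  }
  expect_gte(v_ok / 100, 0.95)
  expect_gte(chain_ok / 100, 0.95)
})

test_that("the exported step functions compose into the pipeline result", {
  d <- simulate_dataset(canned_topology("M2", gamma = 1), n = 1000, seed = 77)
  co <- cor(d)
  roles <- c("variant", "phenotype", "phenotype")
  sk <- learn_skeleton(co, 1000, roles)
  g <- orient_variant_edges(sk$graph)
  vs <- orient_v_structures(g, sk$sepsets, co, 1000, lond = sk$lond,
                            tests = sk$tests)
  fit <- mrpc(d, n_gv = 1)
  expect_true(graph_equal(vs$graph, fit$graph))
  # the extra conditional test joined the same stream: index continues
  expect_gte(vs$lond$i, sk$lond$i)
})

test_that("triple matching follows the basic-model signatures", {
  # M1 analog: V -> T1 fixed, T1 -- T2, V and T2 separated by T1
  g <- mixed_graph(c("V1", "T1", "T2"), 1)
  g <- set_edge(g, "V1", "T1", "directed")
  g <- set_edge(g, "T1", "T2", "undirected")
  tests <- data.frame(index = 1:3, x = c("V1", "V1", "T1"),
                      y = c("T1", "T2", "T2"), S = "",
                      r = c(.5, .3, .5), statistic = 9, p_value = 1e-8,
                      alpha = .01, rejected = TRUE)
  tests <- rbind(tests,
                 data.frame(index = 4, x = "V1", y = "T2", S = "T1", r = 0,
                            statistic = 0, p_value = .9, alpha = .001,
                            rejected = FALSE))
  expect_equal(
    match_pmr_model(g, c("V1", "T1", "T2"), tests,
                    sepsets = list("V1,T2" = "T1")), "B->C")
  # collider analog: V and T2 marginally independent, dependent given T1
  tests$rejected <- c(TRUE, FALSE, TRUE, TRUE)
  tests$p_value <- c(1e-8, .9, 1e-8, 1e-8)
  expect_equal(
    match_pmr_model(g, c("V1", "T1", "T2"), tests,
                    sepsets = list("V1,T2" = character(0))), "C->B")
  # all pairs dependent, no conditional independence, A -> C present: leave
  g4 <- set_edge(g, "V1", "T2", "directed")
  tests$rejected <- TRUE
  expect_equal(match_pmr_model(g4, c("V1", "T1", "T2"), tests,
                               sepsets = list()), "leave")
  # precondition not met
  expect_equal(match_pmr_model(g, c("T2", "T1", "V1"), tests, list()), "none")
})

test_that("symmetric information leaves the phenotype edge unoriented", {
  ok <- 0L
  for (r in 1:50) {
    d <- simulate_dataset(canned_topology("M4", gamma = 1), n = 1000,
                          seed = 700 + r)
    fit <- mrpc(d, n_gv = 1)
    if (edge_mark(fit$graph, "T1", "T2") %in% c("undirected", "bidirected"))
      ok <- ok + 1L
  }
  expect_gte(ok / 50, 0.9)
})

test_that("no output ever points an arrow into a variant", {
  for (nm in c("M2", "M3", "multi_parent", "complex")) {
    topo <- canned_topology(nm, gamma = 0.5, seed = 2)
    n_gv <- sum(topo$graph$roles == "variant")
    for (s in 1:5) {
      d <- simulate_dataset(topo, n = 200, seed = 800 + s)
      fit <- mrpc(d, n_gv = n_gv)
      expect_silent(validate_graph(fit$graph))
    }
  }
})

test_that("the correlation-matrix entry path matches the data path", {
  d <- simulate_dataset(canned_topology("M3", gamma = 1), n = 500, seed = 91)
  f1 <- mrpc(d, n_gv = 1)
  f2 <- mrpc(corr = cor(d), n = 500, n_gv = 1)
  expect_true(graph_equal(f1$graph, f2$graph))
  expect_equal(f1$tests$p_value, f2$tests$p_value)
})

test_that("malformed input is rejected with a useful message", {
  d <- simulate_dataset(canned_topology("M1"), n = 50, seed = 3)
  d[2, 2] <- NA
  expect_error(mrpc(d, n_gv = 1), "missing")
  expect_error(mrpc(corr = diag(3), n = 3, n_gv = 1), "exceed 4")
  expect_error(mrpc(), "supply data")
})

test_that("test log records a coherent LOND stream", {
  d <- simulate_dataset(canned_topology("layered", gamma = 1), n = 500,
                        seed = 15)
  fit <- mrpc(d, n_gv = 1)
  lg <- fit$tests
  expect_equal(lg$index, seq_len(nrow(lg)))
  expect_true(all(lg$rejected == (lg$p_value <= lg$alpha)))
  expect_true(all(abs(lg$r) <= 1))
  expect_equal(sum(lg$rejected), fit$lond$D)
  # alphas follow the closed form given the running rejection count
  D_prev <- c(0, cumsum(lg$rejected))[seq_len(nrow(lg))]
  expect_equal(lg$alpha, fit$lond$c / lg$index^2 * (D_prev + 1))
})
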