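worked_example <- function() {
  truth <- truth_graph("M1")
  g1 <- set_edge(truth, "V1", "T2", "directed")       # extra variant edge
  g2 <- mixed_graph(c("V1", "T1", "T2"), 1)
  g2 <- set_edge(g2, "V1", "T1", "directed")
  g2 <- set_edge(g2, "T1", "T2", "undirected")        # undirected T1-T2
  g3 <- mixed_graph(c("V1", "T1", "T2"), 1)
  g3 <- set_edge(g3, "V1", "T1", "directed")
  g3 <- set_edge(g3, "T2", "T1", "directed")          # reversed T1<-T2
  list(truth = truth, g1 = g1, g2 = g2, g3 = g3)
}

test_that("the worked three-graph example scores 100/50/50", {
  wx <- worked_example()
  s1 <- recall_precision(wx$truth, wx$g1)
  expect_equal(s1$recall, 1); expect_equal(s1$precision, 1)
  s2 <- recall_precision(wx$truth, wx$g2)
  expect_equal(s2$recall, 0.5); expect_equal(s2$precision, 0.5)
  s3 <- recall_precision(wx$truth, wx$g3)
  expect_equal(s3$recall, 0.5); expect_equal(s3$precision, 0.5)
  # without exclusion the spurious variant edge costs precision
  s1b <- recall_precision(wx$truth, wx$g1, exclude_variant_edges = FALSE)
  expect_equal(s1b$recall, 1)
  expect_equal(s1b$precision, 2 / 3)
})

test_that("credits match exhaustive case enumeration on three nodes", {
  # brute-force oracle: truth mark x inferred mark -> credit
  expected <- list(
    directed = c(forward = 1, backward = 0.5, undirected = 0.5,
                 bidirected = 0.5, absent = 0),
    undirected = c(forward = 0.5, backward = 0.5, undirected = 1,
                   bidirected = 1, absent = 0))
  build <- function(mark) {
    g <- mixed_graph(c("V1", "T1", "T2"), 1)
    g <- set_edge(g, "V1", "T1", "directed")
    switch(mark,
           forward = set_edge(g, "T1", "T2", "directed"),
           backward = set_edge(g, "T2", "T1", "directed"),
           undirected = set_edge(g, "T1", "T2", "undirected"),
           bidirected = set_edge(g, "T1", "T2", "bidirected"),
           absent = g)
  }
  for (tm in names(expected)) {
    truth <- build(if (tm == "directed") "forward" else "undirected")
    for (im in names(expected[[tm]])) {
      sc <- recall_precision(truth, build(im))
      expect_equal(sc$recall, unname(expected[[tm]][im]),
                   info = paste(tm, im))
    }
  }
})

test_that("spurious phenotype edges lower precision but not recall", {
  truth <- truth_graph("star")
  inf <- set_edge(truth, "T2", "T3", "directed")
  sc <- recall_precision(truth, inf)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 4 / 5)
  expect_equal(sc$n_inferred, 5L)
})

test_that("scoring is symmetric under joint relabeling and handles 0/0", {
  truth <- truth_graph("M1")
  inf <- worked_example()$g2
  perm <- c("T2", "V1", "T1")
  s <- recall_precision(truth, inf)
  s_perm <- recall_precision(reorder_nodes(truth, perm),
                             reorder_nodes(inf, perm))
  expect_equal(s$recall, s_perm$recall)
  expect_equal(s$precision, s_perm$precision)
  # only variant edges inferred: precision denominator empty
  empty_inf <- set_edge(mixed_graph(c("V1", "T1", "T2"), 1),
                        "V1", "T1", "directed")
  s0 <- recall_precision(truth, empty_inf)
  expect_equal(s0$recall, 0)
  expect_true(is.na(s0$precision))
  expect_error(recall_precision(truth, mixed_graph(c("A", "B"))), "node set")
})

test_that("type-I error counts any phenotype-pair edge under the nulls", {
  g_empty <- mixed_graph(c("V1", "T1", "T2"), 1)
  g_edge <- set_edge(g_empty, "T1", "T2", "directed")
  expect_equal(empirical_type1("M0", list(g_empty, g_empty)), 0)
  expect_equal(empirical_type1("M3", list(g_edge, g_edge)), 1)
  expect_equal(empirical_type1("M0", list(g_edge, g_empty)), 0.5)
  expect_error(empirical_type1("M1", list(g_empty)), "null")
})

test_that("bootstrap proportions are deterministic and well-formed", {
  d <- simulate_dataset(canned_topology("M1", gamma = 1), n = 300, seed = 5)
  b1 <- bootstrap_edge_probs(d, n_gv = 1, B = 1, seed = 9)
  expect_true(all(b1 %in% c(0, 0.5, 1)))
  b <- bootstrap_edge_probs(d, n_gv = 1, B = 25, seed = 9)
  b2 <- bootstrap_edge_probs(d, n_gv = 1, B = 25, seed = 9)
  expect_identical(b, b2)
  expect_true(all(b >= 0 & b <= 1))
  # strong-signal chain: the causal direction dominates the resamples
  expect_gte(b["T1", "T2"], 0.95)
  expect_gte(b["V1", "T1"], 0.95)
})

test_that("grid summaries are medians and SDs over scenario means", {
  one <- data.frame(recall = 0.7, precision = 0.9)
  s <- grid_summary(one)
  expect_equal(s$median, c(0.7, 0.9))
  two <- data.frame(recall = c(0.4, 0.6), precision = c(0.2, 0.8))
  expect_equal(grid_summary(two)$median, c(0.5, 0.5))
  expect_equal(grid_summary(two)$sd,
               c(sd(c(0.4, 0.6)), sd(c(0.2, 0.8))))
})
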