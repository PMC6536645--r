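# Shared fixtures built in code.

# 3x3 correlation matrix with named nodes
cor3 <- function(rxy, rxz, ryz, nodes = c("x", "y", "z")) {
  m <- matrix(c(1, rxy, rxz,
                rxy, 1, ryz,
                rxz, ryz, 1), 3, 3, dimnames = list(nodes, nodes))
  m
}

# truth graph of a canned topology
truth_graph <- function(name, ...) canned_topology(name, ...)$graph

# scripted-decision tester for the three-node universe (V1, T1, T2):
# `deps` is a named logical vector over the keys below; TRUE = dependent
# (p = 0), FALSE = independent (p = 1).
decision_keys <- c("V1,T1", "V1,T2", "T1,T2",
                   "V1,T1|T2", "V1,T2|T1", "T1,T2|V1")
make_stub_tester <- function(deps, nodes = c("V1", "T1", "T2")) {
  function(x, y, S) {
    pr <- nodes[sort(c(x, y))]  # canonical node order, variants first
    key <- paste0(pr[1], ",", pr[2],
                  if (length(S)) paste0("|", nodes[S]) else "")
    dep <- deps[[key]]
    list(r = if (dep) 0.9 else 0, statistic = if (dep) 30 else 0,
         p = if (dep) 0 else 1)
  }
}
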