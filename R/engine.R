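# Internal test engine: a single stream of (conditional) independence tests
# shared by skeleton learning and edge orientation. Every distinct test
# (x, y | S) is run at most once; its decision is cached and reused, so a
# repeated lookup never consumes a fresh LOND significance level.

new_ci_engine <- function(nodes, corr = NULL, n = NULL,
                          lond = lond_state(), tester = NULL) {
  eng <- new.env(parent = emptyenv())
  eng$nodes <- nodes
  eng$corr <- corr
  eng$n <- n
  eng$lond <- lond
  eng$cache <- new.env(parent = emptyenv())
  eng$records <- vector("list", 64L)
  eng$n_records <- 0L
  eng$warned_uninformative <- FALSE
  if (is.null(tester)) {
    if (is.null(corr) || is.null(n)) {
      # lookup-only engine: usable for cached decisions, not for new tests
      tester <- function(x, y, S)
        stop("engine has no data/tester to run new tests")
    } else tester <- function(x, y, S) {
      if (n - length(S) - 3 <= 0) return(NULL)
      r <- partial_correlation(corr, x, y, S)
      ft <- fisher_z_test(r, n, length(S))
      list(r = r, statistic = ft$statistic, p = ft$p_value)
    }
  }
  eng$tester <- tester
  eng
}

test_key <- function(x, y, S) {
  pr <- sort(c(x, y))
  paste(pr[1], pr[2], paste(sort(S), collapse = ","), sep = "|")
}

# Run (or look up) the independence test x _||_ y | S. Node arguments are
# integer indices into eng$nodes. Returns the cached/fresh record, or NULL
# when the test is uninformative (n - |S| - 3 <= 0): the conservative action
# for the caller is then to keep the edge.
engine_test <- function(eng, x, y, S = integer(0)) {
  key <- test_key(x, y, S)
  rec <- eng$cache[[key]]
  if (!is.null(rec)) return(rec)
  res <- eng$tester(x, y, S)
  if (is.null(res)) {
    if (!eng$warned_uninformative) {
      warning("skipping test(s) with n - |S| - 3 <= 0; affected edges ",
              "are kept", call. = FALSE)
      eng$warned_uninformative <- TRUE
    }
    return(NULL)
  }
  out <- lond_record(eng$lond, res$p)
  eng$lond <- out$state
  rec <- list(x = x, y = y, S = S, r = res$r, statistic = res$statistic,
              p = res$p, alpha = out$alpha, rejected = out$rejected,
              index = eng$lond$i)
  eng$cache[[key]] <- rec
  eng$n_records <- eng$n_records + 1L
  if (eng$n_records > length(eng$records))
    eng$records <- c(eng$records, vector("list", length(eng$records)))
  eng$records[[eng$n_records]] <- rec
  rec
}

engine_lookup <- function(eng, x, y, S = integer(0)) {
  eng$cache[[test_key(x, y, S)]]
}

engine_log <- function(eng) {
  recs <- eng$records[seq_len(eng$n_records)]
  if (!length(recs))
    return(data.frame(index = integer(0), x = character(0), y = character(0),
                      S = character(0), r = numeric(0), statistic = numeric(0),
                      p_value = numeric(0), alpha = numeric(0),
                      rejected = logical(0)))
  data.frame(
    index = vapply(recs, `[[`, 0L, "index"),
    x = eng$nodes[vapply(recs, `[[`, 0L, "x")],
    y = eng$nodes[vapply(recs, `[[`, 0L, "y")],
    S = vapply(recs, function(r)
      paste(eng$nodes[r$S], collapse = ","), ""),
    r = vapply(recs, `[[`, 0, "r"),
    statistic = vapply(recs, `[[`, 0, "statistic"),
    p_value = vapply(recs, `[[`, 0, "p"),
    alpha = vapply(recs, `[[`, 0, "alpha"),
    rejected = vapply(recs, `[[`, NA, "rejected"),
    stringsAsFactors = FALSE)
}

# sepsets: environment keyed "i|j" (sorted indices) -> integer vector
sepset_key <- function(x, y) paste(sort(c(x, y)), collapse = "|")
sepset_get <- function(sepsets, x, y) sepsets[[sepset_key(x, y)]]
sepset_set <- function(sepsets, x, y, S) {
  sepsets[[sepset_key(x, y)]] <- S
  invisible(sepsets)
}

sepsets_as_list <- function(sepsets, nodes) {
  keys <- ls(sepsets)
  out <- lapply(keys, function(k) nodes[sepsets[[k]]])
  names(out) <- vapply(strsplit(keys, "|", fixed = TRUE), function(ij)
    paste(nodes[as.integer(ij)], collapse = ","), "")
  out
}
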