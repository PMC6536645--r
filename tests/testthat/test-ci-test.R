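test_that("partial correlation reproduces closed-form and trivial cases", {
  id <- diag(3); dimnames(id) <- rep(list(c("x", "y", "z")), 2)
  expect_equal(partial_correlation(id, "x", "y"), 0)
  r <- cor3(0.5, 0.6, 0.6)
  expect_equal(partial_correlation(r, "x", "y"), 0.5)  # empty S: the entry
  # first-order recursion as independent check:
  # (r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2)) = 0.14/0.64
  expect_equal(partial_correlation(r, "x", "y", "z"), 0.21875)
  expect_equal(partial_correlation(r, "x", "y", "z"),
               (0.5 - 0.36) / sqrt((1 - 0.36) * (1 - 0.36)))
  expect_error(partial_correlation(r, "x", "x", "z"), "distinct")
  sing <- cor3(1, 1, 1)
  expect_error(partial_correlation(sing, "x", "y", "z"), "singular")
})

test_that("partial correlation agrees with residual correlation on samples", {
  # independent oracle: correlate OLS residuals of x|z and y|z
  set.seed(7)
  n <- 5e4
  z <- rnorm(n)
  x <- 0.6 * z + rnorm(n, 0, 0.8)
  y <- 0.6 * z + 0.3 * x + rnorm(n)
  d <- cbind(x = x, y = y, z = z)
  oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
  got <- partial_correlation(cor(d), "x", "y", "z")
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("Fisher's z statistic and p-value behave as printed", {
  ft <- fisher_z_test(0, n = 100)
  expect_equal(ft$statistic, 0)
  expect_equal(ft$p_value, 1)
  # sqrt(97) * atanh(0.5) = sqrt(97) * log(3)/2
  expect_equal(fisher_z_test(0.5, n = 100)$statistic, sqrt(97) * log(3) / 2)
  expect_equal(fisher_z_test(0.5, n = 100)$statistic, 5.410038,
               tolerance = 1e-6)
  expect_error(fisher_z_test(0.5, n = 3), "uninformative")
  expect_error(fisher_z_test(0.5, n = 5, s_size = 2), "uninformative")
  # perfect correlation is clamped, not infinite
  expect_true(is.finite(fisher_z_test(1, n = 100)$statistic))
})

test_that("statistic is odd and p-value even/monotone in the correlation", {
  rs <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  for (r in rs) {
    a <- fisher_z_test(r, 50); b <- fisher_z_test(-r, 50)
    expect_equal(a$statistic, -b$statistic)
    expect_equal(a$p_value, b$p_value)
  }
  p_seq <- vapply(rs, function(r) fisher_z_test(r, 50)$p_value, 0)
  expect_true(all(diff(p_seq) < 0))  # decreasing in |r|
  p_n <- vapply(c(10, 50, 200, 1000),
                function(n) fisher_z_test(0.3, n)$p_value, 0)
  expect_true(all(diff(p_n) < 0))    # decreasing in n at fixed r != 0
})

test_that("test is calibrated under the null (Monte Carlo)", {
  set.seed(101)
  reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(500); y <- rnorm(500)
    rej[i] <- fisher_z_test(cor(x, y), 500)$p_value <= 0.05
  }
  half_width <- qnorm(0.995) * sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), half_width + 1e-12)
})

test_that("large-sample tests reproduce each basic model's signature", {
  # at n = 10,000 and alpha = 0.001, the six pairwise/conditional decisions
  # must equal the d-separation pattern of each model
  sig <- list(  # dependence indicators, keys as in decision_keys
    M0 = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    M1 = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    M2 = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
    M3 = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    M4 = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE))
  for (nm in names(sig)) {
    d <- simulate_dataset(canned_topology(nm, gamma = 1), n = 1e4,
                          seed = match(nm, names(sig)))
    co <- cor(d)
    dec <- c(
      fisher_z_test(partial_correlation(co, "V1", "T1"), 1e4)$p_value,
      fisher_z_test(partial_correlation(co, "V1", "T2"), 1e4)$p_value,
      fisher_z_test(partial_correlation(co, "T1", "T2"), 1e4)$p_value,
      fisher_z_test(partial_correlation(co, "V1", "T1", "T2"), 1e4, 1)$p_value,
      fisher_z_test(partial_correlation(co, "V1", "T2", "T1"), 1e4, 1)$p_value,
      fisher_z_test(partial_correlation(co, "T1", "T2", "V1"), 1e4, 1)$p_value
    ) <= 0.001
    expect_equal(unname(dec), sig[[nm]], info = nm)
  }
})
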