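# LOND ("Levels based on Number of Discoveries") online FDR control.
# The i-th test in the stream is run at
#   alpha_i = delta_i * (D(i-1) + 1),   delta_i = c / i^a,
# where D(i-1) counts rejections among the first i-1 tests and c is chosen
# so that sum_i delta_i = delta, the overall FDR target. For the default
# a = 2, c = 6 * delta / pi^2.

#' Create a LOND controller state
#'
#' @param delta overall FDR target in (0, 1).
#' @param a integer exponent > 1 of the per-test FDR budget `c / i^a`;
#'   larger `a` front-loads the budget and makes the stream more
#'   conservative at later tests.
#' @return an object of class `lond_state`: list with `delta`, `a`, `c`
#'   (normalizing constant), `i` (tests performed) and `D` (rejections).
#' @examples
#' st <- lond_state(0.05)
#' st$c                  # 6 * 0.05 / pi^2 ~ 0.0304
#' lond_next_alpha(st)   # alpha_1 = c
#' @export
lond_state <- function(delta = 0.05, a = 2L) {
  stopifnot(delta > 0, delta < 1, a > 1)
  cc <- if (a == 2) 6 * delta / pi^2 else delta / pracma::zeta(a)
  structure(list(delta = delta, a = a, c = cc, i = 0L, D = 0L),
            class = "lond_state")
}

#' Significance level for the next test in a LOND stream
#'
#' Does not advance the stream; pair with [lond_record()].
#'
#' @param state a `lond_state`.
#' @return `alpha_i = (c / i^a) * (D(i-1) + 1)` for the upcoming index
#'   `i = state$i + 1`.
#' @export
lond_next_alpha <- function(state) {
  i <- state$i + 1L
  (state$c / i^state$a) * (state$D + 1L)
}

#' Record one test in a LOND stream
#'
#' @param state a `lond_state`.
#' @param p_value the test's p-value.
#' @return list with `rejected` (`p <= alpha_i`), `alpha` (the level used)
#'   and `state` (advanced controller).
#' @export
lond_record <- function(state, p_value) {
  if (!is.finite(p_value) || p_value < 0 || p_value > 1)
    stop("p_value must lie in [0, 1]")
  alpha <- lond_next_alpha(state)
  rejected <- p_value <= alpha
  state$i <- state$i + 1L
  if (rejected) state$D <- state$D + 1L
  list(rejected = rejected, alpha = alpha, state = state)
}

#' @export
print.lond_state <- function(x, ...) {
  cat(sprintf(
    "LOND controller: delta = %g, a = %d, c = %.6g; %d tests, %d rejections\n",
    x$delta, x$a, x$c, x$i, x$D))
  invisible(x)
}
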