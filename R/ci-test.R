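# Marginal and conditional independence testing: partial correlation from a
# correlation matrix, Fisher's z transformation, N(0,1) reference under the
# null of (conditional) independence.

#' Partial correlation from a correlation matrix
#'
#' Computes the correlation between `x` and `y` after linearly removing the
#' effect of the conditioning set `S`, using the precision (inverse) of the
#' correlation submatrix over `{x, y} U S`. With empty `S` the marginal
#' entry `corr[x, y]` is returned exactly.
#'
#' @param corr square correlation matrix (symmetric, unit diagonal).
#' @param x,y column names or indices, distinct and not in `S`.
#' @param S conditioning set (names or indices), possibly empty.
#' @return the partial correlation, a scalar in `[-1, 1]`.
#' @examples
#' r <- matrix(c(1, .5, .6, .5, 1, .6, .6, .6, 1), 3,
#'             dimnames = rep(list(c("x", "y", "z")), 2))
#' partial_correlation(r, "x", "y", "z")  # 0.21875
#' @export
partial_correlation <- function(corr, x, y, S = integer(0)) {
  idx <- function(v) if (is.character(v)) match(v, colnames(corr)) else as.integer(v)
  xi <- idx(x); yi <- idx(y); Si <- idx(S)
  if (anyNA(c(xi, yi, Si))) stop("unknown variable name")
  if (xi == yi || xi %in% Si || yi %in% Si)
    stop("x, y and S must be distinct")
  if (length(Si) == 0L) return(corr[xi, yi])
  sub <- corr[c(xi, yi, Si), c(xi, yi, Si)]
  prec <- tryCatch(solve(sub),
                   error = function(e)
                     stop("singular conditioning submatrix for S = {",
                          paste(colnames(corr)[Si], collapse = ", "), "}",
                          call. = FALSE))
  r <- -prec[1, 2] / sqrt(prec[1, 1] * prec[2, 2])
  max(-1, min(1, r))
}

#' Fisher's z test for (conditional) independence
#'
#' The statistic is `sqrt(n - |S| - 3) * atanh(r)`, standard normal under
#' the null of zero (partial) correlation in jointly Gaussian data; the
#' p-value is the two-sided normal tail. `|r|` is clamped at `1 - 1e-12`
#' before the transform so numerically perfect correlation yields a finite,
#' overwhelming statistic instead of infinity.
#'
#' @param r_hat estimated (partial) correlation.
#' @param n sample size.
#' @param s_size size of the conditioning set.
#' @return a list with `statistic` and `p_value`.
#' @examples
#' fisher_z_test(0.5, n = 100)  # statistic ~ 5.41
#' @export
fisher_z_test <- function(r_hat, n, s_size = 0L) {
  df <- n - s_size - 3
  if (df <= 0)
    stop("uninformative test: n - |S| - 3 = ", df, " <= 0")
  r <- max(-1 + 1e-12, min(1 - 1e-12, r_hat))
  stat <- sqrt(df) * 0.5 * log((1 + r) / (1 - r))
  list(statistic = stat, p_value = 2 * stats::pnorm(-abs(stat)))
}
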