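# Beta-weighted iterative robust mean/covariance and the derived robust
# correlation. Each sample receives weight
#   phi_beta(x; mu, v) = exp(-beta/2 * (x - mu)' v^{-1} (x - mu)),
# a decreasing function of its Mahalanobis distance, and the mean and
# covariance are re-estimated as phi-weighted averages until convergence.
# beta = 0 gives every sample weight 1 and reduces to the sample mean and
# the 1/n-scaled covariance.

#' Robust mean and covariance via beta-weighting
#'
#' Iterates the weighted-mean / weighted-scatter fixed point with weights
#' `exp(-beta/2 * d2)` where `d2` is the squared Mahalanobis distance of a
#' sample under the current estimate. The covariance update scales the
#' phi-weighted scatter by `(1 + beta)^(-1) / sum(phi)`; at `beta = 0` this
#' is exactly the 1/n-scaled sample covariance.
#'
#' @param data numeric matrix or data frame, samples in rows; no missing
#'   values (impute beforehand, or supply a correlation matrix to the
#'   learner directly).
#' @param beta downweighting strength in `[0, 1]`; 0 disables robustness,
#'   larger values put smaller weights on outliers. 0.005 is the
#'   conventional choice when contamination is suspected.
#' @param tol convergence tolerance on the max-abs change of mean and
#'   covariance between iterations.
#' @param max_iter iteration cap; non-convergence returns the last iterate
#'   with `converged = FALSE` and a warning.
#' @return object of class `robust_estimate`: list with `mu`, `v` (the
#'   covariance), `weights` (per sample, in (0, 1]), `iterations`,
#'   `converged`.
#' @export
robust_mean_cov <- function(data, beta = 0, tol = 1e-6, max_iter = 100L) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("data must be numeric")
  if (anyNA(x))
    stop("data contains missing values; impute first or pass a ",
         "correlation matrix (corr=, n=) to the learner")
  n <- nrow(x); p <- ncol(x)
  if (n < p + 1L) stop("need at least variables + 1 samples")
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  v <- crossprod(xc) / n
  w <- rep(1, n)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (beta > 0) {
      xc <- sweep(x, 2L, mu)
      sol <- tryCatch(solve(v, t(xc)), error = function(e)
        stop("singular covariance during robust iteration", call. = FALSE))
      d2 <- colSums(t(xc) * sol)
      w <- exp(-beta / 2 * d2)
    }
    sw <- sum(w)
    mu_new <- colSums(x * w) / sw
    xc <- sweep(x, 2L, mu)  # scatter about the current (old) mean
    v_new <- crossprod(xc * sqrt(w)) / ((1 + beta) * sw)
    delta <- max(max(abs(mu_new - mu)), max(abs(v_new - v)))
    mu <- mu_new; v <- v_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    warning("robust_mean_cov did not converge in ", max_iter, " iterations")
  dimnames(v) <- list(colnames(x), colnames(x))
  names(mu) <- colnames(x)
  structure(list(mu = mu, v = v, weights = w, iterations = iter,
                 converged = converged, beta = beta),
            class = "robust_estimate")
}

#' @export
print.robust_estimate <- function(x, ...) {
  cat(sprintf(
    "Robust estimate (beta = %g): %d variables, %d samples, %d iteration(s)%s\n",
    x$beta, length(x$mu), length(x$weights), x$iterations,
    if (x$converged) "" else " [not converged]"))
  cat("weight range:", sprintf("%.4f", min(x$weights)), "-",
      sprintf("%.4f", max(x$weights)), "\n")
  invisible(x)
}

#' Robust correlation matrix
#'
#' Normalizes the robust covariance of [robust_mean_cov()] by its diagonal.
#' At `beta = 0` this equals the Pearson correlation matrix (the 1/n scalar
#' cancels).
#'
#' @inheritParams robust_mean_cov
#' @return correlation matrix with unit diagonal.
#' @export
robust_correlation <- function(data, beta = 0, tol = 1e-6, max_iter = 100L) {
  est <- robust_mean_cov(data, beta = beta, tol = tol, max_iter = max_iter)
  d <- diag(est$v)
  if (any(d <= 0))
    stop("zero-variance column: ",
         paste(colnames(est$v)[d <= 0], collapse = ", "))
  r <- est$v / tcrossprod(sqrt(d))
  diag(r) <- 1
  r
}
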