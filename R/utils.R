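#' Shortest empirical highest-posterior-density interval
#'
#' Computes the shortest interval containing a given probability mass of the
#' empirical distribution of `x`, the usual summary for MCMC output.
#'
#' @param x numeric vector of posterior draws.
#' @param prob target coverage, default 0.95.
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  stopifnot(is.numeric(x), length(x) >= 2, prob > 0, prob < 1)
  xs <- sort(x)
  n <- length(xs)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(xs[1L], xs[n]))
  widths <- xs[(k + 1L):n] - xs[1L:(n - k)]
  i <- which.min(widths)
  c(xs[i], xs[i + k])
}

# half-vectorization of a symmetric matrix (column-major lower triangle)
vech <- function(m) m[lower.tri(m, diag = TRUE)]

# inverse of vech for an m x m symmetric matrix
unvech <- function(v, m) {
  out <- matrix(0, m, m)
  out[lower.tri(out, diag = TRUE)] <- v
  out <- out + t(out)
  diag(out) <- diag(out) / 2
  out
}

# symmetric matrix square root; tolerates PSD input (clamps eigenvalues
# above -tol to zero), errors on genuinely indefinite matrices
mat_sqrt <- function(m, tol = 1e-8) {
  if (length(m) == 1L) m <- matrix(m, 1, 1)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  ref <- max(abs(e$values), 1)
  if (min(e$values) < -tol * ref)
    stop("matrix is not positive semidefinite (min eigenvalue ",
         format(min(e$values)), ")")
  ev <- pmax(e$values, 0)
  e$vectors %*% (sqrt(ev) * t(e$vectors))
}

softmax <- function(x) {
  z <- exp(x - max(x[is.finite(x)]))
  z[!is.finite(x)] <- 0
  z / sum(z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Gaussian log-density with covariance given through its Cholesky factor
# (upper triangular, as returned by chol())
ldmvnorm_chol <- function(resid, cholV) {
  z <- backsolve(cholV, resid, transpose = TRUE)
  -0.5 * (length(resid) * log(2 * pi) + 2 * sum(log(diag(cholV))) + sum(z^2))
}

# deterministic per-stage seeds derived from one master seed (kept < 2^31)
derive_seed <- function(seed, stage) {
  (as.integer(seed) + 7919L * as.integer(stage)) %% 2147483647L
}
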