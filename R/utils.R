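# Internal numeric helpers shared across modules.

#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Elementwise log(exp(a) + exp(b)) for two vectors; -Inf-safe.
logadd <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# Log-density of rows of X under a full-covariance Gaussian.
dmvnorm_log <- function(X, mu, Sigma) {
  X <- rbind(X)
  d <- length(mu)
  ch <- chol(Sigma)
  z <- forwardsolve(t(ch), t(X) - mu)
  -0.5 * (d * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# Log-density of rows of X under a diagonal-covariance Gaussian.
# mu, var are d-vectors.
dmvnorm_diag_log <- function(X, mu, var) {
  X <- rbind(X)
  d <- length(mu)
  z2 <- sweep(X, 2, mu)^2
  -0.5 * (d * log(2 * pi) + sum(log(var))) - 0.5 * drop(z2 %*% (1 / var))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x) || nrow(x) < 1L)
    stop(sprintf("'%s' must be a non-empty numeric matrix (frames in rows)", name))
  if (any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name))
  invisible(x)
}
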