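# Heteroscedastic linear discriminant analysis. An n x n linear map
# Theta is estimated by maximum likelihood under the model in which the
# first p projected dimensions carry class-dependent diagonal variances
# (the discriminative subspace) and the remaining n - p dimensions carry
# a single shared distribution (nuisance). Estimation uses the
# generalized-EM row-wise cofactor updates of Gales; initialization is
# the LDA solution.

#' Per-class and global moment statistics
#'
#' Accumulates exact sample moments (population 1/N convention) per class
#' and globally from labeled frames. These are the sufficient statistics
#' for the HLDA objective, so estimation never needs a second pass over
#' the data.
#'
#' @param X Feature matrix (frames in rows) or list of matrices.
#' @param labels Class id per frame (factor/character/integer), matching
#'   the row count of `X` (concatenated, for a list).
#' @return An object of class `class_stats`: per-class counts, means and
#'   covariances, plus global count, mean and total covariance.
#' @export
accumulate_stats <- function(X, labels) {
  if (is.list(X) && !is.matrix(X)) X <- do.call(rbind, X)
  stopifnot_matrix(X)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) stop("one label per frame required")
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("at least 2 classes are required for discrimination")
  n <- ncol(X); N <- nrow(X)
  counts <- numeric(length(classes)); names(counts) <- classes
  means <- matrix(0, length(classes), n, dimnames = list(classes, colnames(X)))
  covs <- array(0, c(n, n, length(classes)), dimnames = list(NULL, NULL, classes))
  low <- character()
  for (k in seq_along(classes)) {
    Xk <- X[labels == classes[k], , drop = FALSE]
    counts[k] <- nrow(Xk)
    means[k, ] <- colMeans(Xk)
    covs[, , k] <- crossprod(sweep(Xk, 2, means[k, ])) / nrow(Xk)
    if (nrow(Xk) < n) low <- c(low, classes[k])
  }
  if (length(low) > 0L)
    warning("class(es) with fewer frames than dimensions (covariance will be ",
            "diagonally loaded): ", paste(low, collapse = ", "))
  gmean <- colMeans(X)
  gcov <- crossprod(sweep(X, 2, gmean)) / N
  structure(list(classes = classes, counts = counts, means = means,
                 covs = covs, N = N, n = n, mean = gmean, cov = gcov),
            class = "class_stats")
}

#' @export
print.class_stats <- function(x, ...) {
  cat(sprintf("<class_stats: %d classes, %d frames, %d dims>\n",
              length(x$classes), x$N, x$n))
  invisible(x)
}

load_diag <- function(S, frac = 1e-6) {
  S + diag(frac * sum(diag(S)) / nrow(S), nrow(S))
}

# HLDA log-likelihood with the ML diagonal variances plugged in for a
# given Theta; covariances passed explicitly so the estimator can use
# diagonally loaded versions consistently.
hlda_objective_raw <- function(Theta, counts, covs_l, Tcov, N, p) {
  n <- nrow(Theta)
  ldet <- as.numeric(determinant(Theta, logarithm = TRUE)$modulus)
  ll <- N * ldet - N * n / 2 * log(2 * pi) - N * n / 2
  for (j in seq_len(n)) {
    th <- Theta[j, ]
    if (j <= p) {
      for (k in seq_along(covs_l)) {
        v <- drop(th %*% covs_l[[k]] %*% th)
        ll <- ll - counts[k] / 2 * log(v)
      }
    } else {
      v <- drop(th %*% Tcov %*% th)
      ll <- ll - N / 2 * log(v)
    }
  }
  unname(ll)
}

hlda_objective <- function(Theta, stats, p) {
  covs <- lapply(seq_along(stats$classes), function(k) stats$covs[, , k])
  hlda_objective_raw(Theta, stats$counts, covs, stats$cov, stats$N, p)
}

#' HLDA model log-likelihood of the training data
#'
#' Evaluates the HLDA objective (total log-likelihood of all frames under
#' the class-conditional Gaussian model in the transformed space, with
#' maximum-likelihood diagonal variances) from sufficient statistics
#' alone.
#'
#' @param transform An `hlda` object (or bare `n x n` matrix with `p`).
#' @param stats A `class_stats` object from [accumulate_stats()].
#' @param p Retained dimensionality (taken from `transform` if an `hlda`).
#' @return Scalar log-likelihood.
#' @export
hlda_loglik <- function(transform, stats, p = NULL) {
  if (inherits(transform, "hlda")) {
    p <- transform$p
    Theta <- transform$Theta
  } else Theta <- transform
  if (is.null(p)) stop("p must be supplied for a bare matrix")
  for (k in seq_along(stats$classes))
    if (min(eigen(stats$covs[, , k], symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("class covariance not positive semi-definite")
  hlda_objective(Theta, stats, p)
}

# LDA initialization: generalized eigenvectors of (within, between),
# eigenvalue ties broken by index through eigen()'s fixed ordering.
lda_init <- function(stats) {
  n <- stats$n
  W <- matrix(0, n, n)
  for (k in seq_along(stats$classes))
    W <- W + stats$counts[k] * stats$covs[, , k]
  W <- W / stats$N
  B <- stats$cov - W                    # between-class scatter = total - within
  L <- t(chol(load_diag(W)))
  M <- solve(L, t(solve(L, t((B + t(B)) / 2))))
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  V <- solve(t(L), eg$vectors)
  Theta <- t(V)
  Theta / sqrt(rowSums(Theta^2))
}

#' Estimate an HLDA transformation
#'
#' Maximum-likelihood estimation of the n x n transformation whose first
#' `p` rows span the class-discriminative subspace. Starts from the LDA
#' solution and applies row-wise generalized-EM updates: each row is
#' replaced by the scaled cofactor direction `c_j G_j^{-1}`, which
#' maximizes the objective with all other rows held fixed, so the
#' objective is non-decreasing at every update.
#'
#' @param stats A `class_stats` object.
#' @param p Retained dimensionality (`p <= n`).
#' @param n_iters Maximum number of full row-update sweeps.
#' @param tol Relative objective change below which iteration stops.
#' @return An object of class `hlda`: `Theta`, `p`, `n`, and the
#'   per-sweep objective `trace`.
#' @export
estimate_hlda <- function(stats, p, n_iters = 100L, tol = 1e-6) {
  if (!inherits(stats, "class_stats")) stop("stats must come from accumulate_stats()")
  n <- stats$n
  if (p < 1L || p > n) stop("p must be in 1..n")
  covs_l <- lapply(seq_along(stats$classes), function(k) load_diag(stats$covs[, , k]))
  Tcov <- load_diag(stats$cov)
  Theta <- lda_init(stats)
  obj <- hlda_objective_raw(Theta, stats$counts, covs_l, Tcov, stats$N, p)
  trace <- obj
  for (sweep_i in seq_len(n_iters)) {
    Thinv <- solve(Theta)
    for (j in seq_len(n)) {
      cj <- Thinv[, j]                 # cofactor direction of row j
      th <- Theta[j, ]
      if (j <= p) {
        Gj <- matrix(0, n, n)
        for (k in seq_along(stats$classes)) {
          v <- drop(th %*% covs_l[[k]] %*% th)
          Gj <- Gj + (stats$counts[k] / v) * covs_l[[k]]
        }
      } else {
        v <- drop(th %*% Tcov %*% th)
        Gj <- (stats$N / v) * Tcov
      }
      dir <- solve(Gj, cj)
      scale <- sqrt(stats$N / drop(cj %*% dir))
      Theta[j, ] <- dir * scale
      Thinv <- solve(Theta)
    }
    obj_new <- hlda_objective_raw(Theta, stats$counts, covs_l, Tcov, stats$N, p)
    trace <- c(trace, obj_new)
    if (abs(obj_new - obj) <= tol * abs(obj)) { obj <- obj_new; break }
    obj <- obj_new
  }
  structure(list(Theta = Theta, p = as.integer(p), n = as.integer(n),
                 trace = trace), class = "hlda")
}

#' @export
print.hlda <- function(x, ...) {
  cat(sprintf("<hlda: %d -> %d, objective %.4f after %d sweeps>\n",
              x$n, x$p, x$trace[length(x$trace)], length(x$trace) - 1L))
  invisible(x)
}

#' Project features into the retained HLDA subspace
#'
#' Applies the first `p` rows of the transformation: `y = Theta_p x`.
#'
#' @param transform An `hlda` object.
#' @param X An n-vector or matrix with n columns (frames in rows).
#' @return A p-vector or `T x p` matrix.
#' @export
hlda_project <- function(transform, X) {
  if (!inherits(transform, "hlda")) stop("transform must be an hlda object")
  single <- is.null(dim(X))
  X <- rbind(X)
  if (ncol(X) != transform$n)
    stop("input has ", ncol(X), " columns; transform expects ", transform$n)
  Y <- X %*% t(transform$Theta[seq_len(transform$p), , drop = FALSE])
  colnames(Y) <- paste0("h", seq_len(transform$p))
  if (single) drop(Y) else Y
}

#' @rdname hlda_project
#' @param object,newdata,... `predict` interface.
#' @export
predict.hlda <- function(object, newdata, ...) hlda_project(object, newdata)
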