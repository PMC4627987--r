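# Joint-density GMM voice conversion. The mixture over stacked
# source/target vectors z = [x, y] is estimated directly from
# vector-quantized data (k-means classes, then per-class weights, means
# and full joint covariances), not by EM. Each component's covariance
# blocks give a local linear regression of y on x; the conversion
# function is the posterior-weighted mixture of those regressions,
# i.e. the conditional expectation E[y | x].

#' Lloyd k-means with deterministic empty-cluster repair
#'
#' Vector quantization used to initialize the joint-GMM classes. Runs
#' Lloyd's algorithm from a seeded random subset of points; a cluster
#' that empties is re-seeded from the point currently farthest from its
#' assigned centroid, so exactly `G` live classes are returned.
#'
#' @param Z Data matrix (rows = joint vectors).
#' @param G Number of classes.
#' @param seed Integer seed; the run is deterministic given it.
#' @param max_iter Maximum Lloyd iterations.
#' @return List with `assignment` (integer vector in 1..G) and
#'   `centroids` (`G x d`).
#' @export
kmeans_init <- function(Z, G, seed = 1L, max_iter = 100L) {
  stopifnot_matrix(Z)
  n <- nrow(Z)
  if (G < 1L || G > n) stop("G must be between 1 and the number of vectors")
  set.seed(seed)
  centroids <- Z[sample.int(n, G), , drop = FALSE]
  zz <- rowSums(Z^2)
  assignment <- rep(0L, n)
  for (iter in seq_len(max_iter)) {
    d2 <- outer(zz, rowSums(centroids^2), `+`) - 2 * Z %*% t(centroids)
    new_assign <- max.col(-d2, ties.method = "first")
    dist_own <- d2[cbind(seq_len(n), new_assign)]
    # repair empty clusters from the worst-fitting points
    for (g in which(tabulate(new_assign, G) == 0L)) {
      far <- which.max(dist_own)
      new_assign[far] <- g
      dist_own[far] <- -Inf
      centroids[g, ] <- Z[far, ]
    }
    if (identical(new_assign, assignment)) break
    assignment <- new_assign
    for (g in seq_len(G))
      centroids[g, ] <- colMeans(Z[assignment == g, , drop = FALSE])
  }
  list(assignment = assignment, centroids = centroids)
}

#' Estimate a joint-density GMM from classified mapping vectors
#'
#' Given joint vectors `z = [x, y]` and a hard class assignment, computes
#' for each class i the weight `alpha_i = N_i / N`, the stacked mean
#' (per-class sample mean) and the full joint sample covariance
#' (population 1/N convention), whose blocks are the source, target and
#' cross covariances. A variance floor proportional to the global
#' variance is added to covariance diagonals.
#'
#' @param Z `N x (dx + dy)` matrix of joint vectors.
#' @param assignment Integer class labels in 1..G (every class non-empty).
#' @param dx Source dimensionality (default half of `ncol(Z)`).
#' @param var_floor Diagonal floor as a fraction of global variance.
#' @return An object of class `joint_gmm`.
#' @export
estimate_joint_gmm <- function(Z, assignment, dx = ncol(Z) %/% 2L,
                               var_floor = 1e-4) {
  stopifnot_matrix(Z)
  G <- max(assignment)
  if (any(tabulate(assignment, G) == 0L)) stop("every class must be non-empty")
  n <- nrow(Z); d <- ncol(Z)
  floor_diag <- var_floor * mean(apply(Z, 2, stats::var))
  alpha <- tabulate(assignment, G) / n
  mu <- matrix(0, G, d)
  Sigma <- array(0, c(d, d, G))
  small <- 0L
  for (g in seq_len(G)) {
    Zg <- Z[assignment == g, , drop = FALSE]
    mu[g, ] <- colMeans(Zg)
    C <- crossprod(sweep(Zg, 2, mu[g, ])) / nrow(Zg)
    if (nrow(Zg) < 2L) small <- small + 1L
    # floor, not additive load: healthy variances are left untouched so the
    # per-component regressions stay exact on well-conditioned classes
    diag(C) <- pmax(diag(C), floor_diag)
    Sigma[, , g] <- (C + t(C)) / 2
  }
  if (small > 0L)
    warning(small, " class(es) with fewer than 2 members: covariance is the floor")
  structure(list(G = G, dx = dx, dy = d - dx, alpha = alpha, mu = mu,
                 Sigma = Sigma), class = "joint_gmm")
}

#' @export
print.joint_gmm <- function(x, ...) {
  cat(sprintf("<joint_gmm: %d components, %d+%d dims>\n", x$G, x$dx, x$dy))
  invisible(x)
}

#' Component posterior probabilities of source vectors
#'
#' `p(i | x) = alpha_i N(x; mu_i^x, Sigma_i^xx) / sum_j ...`, computed in
#' the log domain. Rows sum to 1.
#'
#' @param gmm A `joint_gmm`.
#' @param X Source vectors, one per row (or a single vector).
#' @return An `n x G` matrix of posteriors.
#' @export
gmm_posterior <- function(gmm, X) {
  X <- rbind(X)
  if (ncol(X) != gmm$dx) stop("source vectors must have ", gmm$dx, " components")
  if (any(!is.finite(X))) stop("non-finite source vector")
  ix <- seq_len(gmm$dx)
  lp <- vapply(seq_len(gmm$G), function(g) {
    log(gmm$alpha[g]) +
      dmvnorm_log(X, gmm$mu[g, ix], gmm$Sigma[ix, ix, g])
  }, numeric(nrow(X)))
  lp <- matrix(lp, nrow(X), gmm$G)
  m <- apply(lp, 1, max)
  p <- exp(lp - m)
  p / rowSums(p)
}

#' Build the conversion function from a joint GMM
#'
#' Precomputes, for each component, the regression
#' `y ~ mu_i^y + Sigma_i^yx (Sigma_i^xx)^{-1} (x - mu_i^x)` so that
#' conversion is the posterior-weighted sum of affine maps.
#'
#' @param gmm A `joint_gmm`.
#' @return An object of class `conversion_function`.
#' @export
conversion_function <- function(gmm) {
  ix <- seq_len(gmm$dx); iy <- gmm$dx + seq_len(gmm$dy)
  A <- vector("list", gmm$G)
  b <- matrix(0, gmm$G, gmm$dy)
  for (g in seq_len(gmm$G)) {
    Sxx <- gmm$Sigma[ix, ix, g]
    Syx <- gmm$Sigma[iy, ix, g, drop = TRUE]
    Ag <- t(solve(Sxx, t(rbind(Syx))))
    A[[g]] <- Ag
    b[g, ] <- gmm$mu[g, iy] - Ag %*% gmm$mu[g, ix]
  }
  structure(list(gmm = gmm, A = A, b = b), class = "conversion_function")
}

#' @export
print.conversion_function <- function(x, ...) {
  cat(sprintf("<conversion_function: %d components, %d -> %d dims>\n",
              x$gmm$G, x$gmm$dx, x$gmm$dy))
  invisible(x)
}

#' Convert source vectors into the target feature space
#'
#' Evaluates the conditional expectation `F(x) = E[y | x]` under the
#' joint GMM: the posterior-weighted mixture of per-component linear
#' regressions.
#'
#' @param fn A `conversion_function`.
#' @param X Source vectors, one per row (or a single vector).
#' @return Converted vectors, same number of rows, `dy` columns.
#' @export
convert <- function(fn, X) {
  if (!inherits(fn, "conversion_function")) stop("fn must be a conversion_function")
  single <- is.null(dim(X))
  X <- rbind(X)
  P <- gmm_posterior(fn$gmm, X)
  out <- matrix(0, nrow(X), fn$gmm$dy)
  for (g in seq_len(fn$gmm$G)) {
    reg <- X %*% t(fn$A[[g]])
    reg <- sweep(reg, 2, fn$b[g, ], `+`)
    out <- out + P[, g] * reg
  }
  if (single) drop(out) else out
}

#' @rdname convert
#' @param object,newdata,... `predict` interface: `newdata` as in `X`.
#' @export
predict.conversion_function <- function(object, newdata, ...) convert(object, newdata)

# Hard re-assignment passes in joint space (vector-quantization flavour of
# the direct statistical estimation): alternate nearest-mean classification
# and moment re-estimation until the partition stabilizes.
ise2d_refine <- function(Z, assignment, dx, max_pass = 20L, var_floor = 1e-4) {
  G <- max(assignment)
  zz <- rowSums(Z^2)
  for (pass in seq_len(max_pass)) {
    gmm <- estimate_joint_gmm(Z, assignment, dx, var_floor)
    d2 <- outer(zz, rowSums(gmm$mu^2), `+`) - 2 * Z %*% t(gmm$mu)
    new_assign <- max.col(-d2, ties.method = "first")
    dist_own <- d2[cbind(seq_len(nrow(Z)), new_assign)]
    for (g in which(tabulate(new_assign, G) == 0L)) {
      far <- which.max(dist_own)
      new_assign[far] <- g
      dist_own[far] <- -Inf
    }
    if (identical(new_assign, assignment)) break
    assignment <- new_assign
  }
  estimate_joint_gmm(Z, assignment, dx, var_floor)
}

#' Train a voice-conversion function on parallel corpora
#'
#' Full training loop over parallel source/target utterance lists of
#' static cepstral frames. Iteration 1 aligns source with target by DTW
#' and estimates the joint GMM from the pooled mapping list (k-means
#' classes, then direct statistical estimation with hard re-assignment).
#' From iteration 2 on, the DTW alignment is recomputed between the
#' *converted* source frames and the target to refine the mapping list,
#' and the model is re-estimated. The model with the lowest mean squared
#' conversion error over the aligned training pairs is returned.
#'
#' @param src,tgt Lists of `T x d` static feature matrices (parallel:
#'   element i of each is the same sentence).
#' @param G Number of mixture components (classes).
#' @param n_outer Number of outer alignment/estimation iterations.
#' @param seed Integer seed for the k-means initialization.
#' @param var_floor Covariance diagonal floor fraction.
#' @param verbose Print the per-iteration mean squared error.
#' @return A `conversion_function` with attribute `trace` (data frame of
#'   per-iteration mean squared error and mapping-list size).
#' @export
train_conversion <- function(src, tgt, G = 64L, n_outer = 3L, seed = 1L,
                             var_floor = 1e-4, verbose = FALSE) {
  if (!is.list(src) || !is.list(tgt)) stop("src and tgt must be lists of matrices")
  if (length(src) != length(tgt))
    stop("corpora are not parallel: ", length(src), " vs ", length(tgt), " sentences")
  if (length(src) == 0L) stop("empty corpus")
  dx <- ncol(src[[1]])
  mse <- function(fn) {
    tot <- 0; n <- 0
    for (s in seq_along(src)) {
      pr <- dtw_align(convert(fn, src[[s]]), tgt[[s]])$pairs
      err <- convert(fn, src[[s]])[pr[, 1], , drop = FALSE] -
        tgt[[s]][pr[, 2], , drop = FALSE]
      tot <- tot + sum(err^2); n <- n + nrow(err)
    }
    tot / n
  }
  best <- NULL; best_mse <- Inf
  trace <- data.frame(iteration = integer(), mse = numeric(), n_pairs = integer())
  fn <- NULL
  for (it in seq_len(n_outer)) {
    Zs <- vector("list", length(src))
    for (s in seq_along(src)) {
      left <- if (it == 1L) src[[s]] else convert(fn, src[[s]])
      path <- dtw_align(left, tgt[[s]])
      # joint vectors always pair the *original* source frame with the target
      Zs[[s]] <- build_mapping_list(src[[s]], tgt[[s]], path)
    }
    Z <- do.call(rbind, Zs)
    km <- kmeans_init(Z, G, seed = seed + it - 1L)
    gmm <- ise2d_refine(Z, km$assignment, dx, var_floor = var_floor)
    fn <- conversion_function(gmm)
    m <- mse(fn)
    trace <- rbind(trace, data.frame(iteration = it, mse = m, n_pairs = nrow(Z)))
    if (verbose) message(sprintf("iteration %d: %d pairs, mse %.6f", it, nrow(Z), m))
    if (m < best_mse) { best <- fn; best_mse <- m }
    if (it > 1L) {
      prev <- trace$mse[it - 1L]
      if (is.finite(prev) && abs(prev - m) / max(prev, 1e-12) < 1e-4) break
    }
  }
  attr(best, "trace") <- trace
  best
}
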