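# Monophone HMM/GMM acoustic models: 5 states per phone (entry, 3
# emitting, exit), strictly left-to-right with self-loops, diagonal
# Gaussian mixture emissions (up to 16 components per state). Training
# is embedded Baum-Welch over phone-concatenated utterance models, with
# flat-start initialization and binary mixture splitting.

#' Flat-start initialization of a monophone HMM set
#'
#' Every emitting state of every phone model is initialized to a single
#' Gaussian with the global mean and variance of the training frames;
#' transition rows get uniform probability over the legal left-to-right
#' arcs (self and forward).
#'
#' @param phones Character vector of phone labels (the inventory).
#' @param feats List of feature matrices (or one matrix) supplying the
#'   global statistics.
#' @return An object of class `phone_hmm_set`.
#' @export
flat_start <- function(phones, feats) {
  if (is.matrix(feats)) feats <- list(feats)
  if (length(feats) == 0L) stop("empty corpus")
  X <- do.call(rbind, feats)
  stopifnot_matrix(X)
  d <- ncol(X)
  gmean <- colMeans(X)
  gvar <- apply(X, 2, stats::var)
  trans <- matrix(0, 5, 5)
  trans[1, 2] <- 1
  for (s in 2:4) { trans[s, s] <- 0.5; trans[s, s + 1] <- 0.5 }
  gmm1 <- list(w = 1, mu = matrix(gmean, 1), var = matrix(gvar, 1))
  mod <- list(trans = trans, gmms = list(gmm1, gmm1, gmm1))
  models <- stats::setNames(rep(list(mod), length(phones)), phones)
  structure(list(phones = phones, dim = d, models = models,
                 global_var = gvar), class = "phone_hmm_set")
}

#' @export
print.phone_hmm_set <- function(x, ...) {
  nmix <- max(vapply(x$models, function(m) max(lengths(lapply(m$gmms, `[[`, "w"))),
                     numeric(1)))
  cat(sprintf("<phone_hmm_set: %d phones, dim %d, up to %d Gaussians/state>\n",
              length(x$phones), x$dim, nmix))
  invisible(x)
}

# Log-likelihood of every frame under every mixture component of a GMM
# (T x K), plus the state-level mixture log-likelihood (T vector).
gmm_state_loglik <- function(gmm, X) {
  K <- length(gmm$w)
  ivar <- 1 / gmm$var                              # K x d
  const <- -0.5 * (ncol(X) * log(2 * pi) + rowSums(log(gmm$var)) +
                     rowSums(gmm$mu^2 * ivar))
  comp <- X^2 %*% t(-0.5 * ivar) + X %*% t(gmm$mu * ivar)
  comp <- sweep(comp, 2, const, `+`)
  comp <- sweep(comp, 2, log(gmm$w), `+`)
  if (K == 1L) list(comp = comp, state = comp[, 1])
  else {
    m <- do.call(pmax, as.data.frame(comp))
    state <- m + log(rowSums(exp(comp - m)))
    list(comp = comp, state = state)
  }
}

# T x (3 * n_phones) matrix of per-state emission log-likelihoods.
emission_logliks <- function(hset, X, phones = hset$phones) {
  out <- matrix(0, nrow(X), 3L * length(phones))
  for (p in seq_along(phones)) {
    m <- hset$models[[phones[p]]]
    for (s in 1:3)
      out[, (p - 1L) * 3L + s] <- gmm_state_loglik(m$gmms[[s]], X)$state
  }
  out
}

# Composite linear-chain parameters for one transcribed utterance:
# J = 3M states, each with a self log-prob and the log-prob of the arc
# from its predecessor (within-phone forward, or previous phone's exit).
composite_chain <- function(hset, phone_seq) {
  M <- length(phone_seq)
  J <- 3L * M
  lself <- numeric(J); lprev <- numeric(J)
  for (m in seq_len(M)) {
    tr <- hset$models[[phone_seq[m]]]$trans
    for (s in 1:3) {
      j <- (m - 1L) * 3L + s
      lself[j] <- log(tr[s + 1, s + 1])
      lprev[j] <- if (s > 1L) log(tr[s, s + 1])
        else if (m == 1L) -Inf                      # entered via initial state
        else log(hset$models[[phone_seq[m - 1L]]]$trans[4, 5])
    }
  }
  lexit <- log(hset$models[[phone_seq[M]]]$trans[4, 5])
  list(J = J, lself = lself, lprev = lprev, lexit = lexit,
       phone_of = rep(seq_len(M), each = 3L), state_of = rep(1:3, M))
}

#' Forward-backward pass over one transcribed utterance
#'
#' Runs the scaled (log-domain) forward and backward recursions over the
#' linear chain obtained by concatenating the phone models of the
#' transcription. Exposed primarily so the two total-likelihood routes
#' can be compared and state posteriors inspected.
#'
#' @param hset A `phone_hmm_set`.
#' @param X Feature matrix of the utterance (frames in rows).
#' @param phone_seq Character vector: the phone transcription.
#' @return List with `log_alpha`, `log_beta`, `gamma` (state posteriors),
#'   `loglik_forward`, `loglik_backward`, and the chain description.
#' @export
forward_backward <- function(hset, X, phone_seq) {
  stopifnot_matrix(X)
  if (length(phone_seq) < 1L) stop("empty transcription")
  if (!all(phone_seq %in% hset$phones))
    stop("unknown phone label(s): ",
         paste(setdiff(phone_seq, hset$phones), collapse = ", "))
  ch <- composite_chain(hset, phone_seq)
  T_ <- nrow(X); J <- ch$J
  if (T_ < length(phone_seq) * 3L)
    stop("utterance too short to traverse its transcription (",
         T_, " frames for ", J, " emitting states)")
  logb_state <- emission_logliks(hset, X, unique(phone_seq))
  cols <- (match(phone_seq, unique(phone_seq))[ch$phone_of] - 1L) * 3L + ch$state_of
  logb <- logb_state[, cols, drop = FALSE]

  la <- matrix(-Inf, T_, J)
  la[1, 1] <- logb[1, 1]
  for (t in 2:T_) {
    stay <- la[t - 1, ] + ch$lself
    move <- c(-Inf, la[t - 1, -J]) + ch$lprev
    la[t, ] <- logadd(stay, move) + logb[t, ]
  }
  lb <- matrix(-Inf, T_, J)
  lb[T_, J] <- ch$lexit
  for (t in (T_ - 1):1) {
    stay <- ch$lself + logb[t + 1, ] + lb[t + 1, ]
    move <- c(ch$lprev[-1], -Inf) + c(logb[t + 1, -1], -Inf) + c(lb[t + 1, -1], -Inf)
    lb[t, ] <- logadd(stay, move)
  }
  ll_f <- la[T_, J] + ch$lexit
  ll_b <- logb[1, 1] + lb[1, 1]
  gamma <- exp(la + lb - ll_f)
  list(log_alpha = la, log_beta = lb, gamma = gamma, logb = logb,
       loglik_forward = ll_f, loglik_backward = ll_b, chain = ch)
}

#' Embedded Baum-Welch re-estimation
#'
#' Maximum-likelihood re-estimation of all phone models from transcribed
#' utterances: each utterance's phone models are concatenated into one
#' left-to-right chain, state and mixture occupancies are accumulated
#' with forward-backward, and means, variances (floored), mixture
#' weights and transition probabilities are updated. The total data
#' log-likelihood is non-decreasing across iterations.
#'
#' @param hset A `phone_hmm_set`.
#' @param feats List of feature matrices.
#' @param transcriptions List of phone-label vectors, parallel to `feats`.
#' @param n_iter Number of re-estimation iterations.
#' @param var_floor_frac Per-dimension variance floor as a fraction of
#'   the global variance.
#' @return The updated `phone_hmm_set`, with attribute `loglik_trace`.
#' @export
baum_welch <- function(hset, feats, transcriptions, n_iter = 5L,
                       var_floor_frac = 1e-2) {
  if (length(feats) != length(transcriptions))
    stop("feats and transcriptions must be parallel lists")
  floor_v <- var_floor_frac * hset$global_var
  d <- hset$dim
  trace <- numeric(0)
  for (iter in seq_len(n_iter)) {
    acc <- list()
    for (ph in hset$phones) {
      K <- vapply(hset$models[[ph]]$gmms, function(g) length(g$w), integer(1))
      acc[[ph]] <- list(
        occ = lapply(K, function(k) numeric(k)),
        sx = lapply(K, function(k) matrix(0, k, d)),
        sx2 = lapply(K, function(k) matrix(0, k, d)),
        self = numeric(3), fwd = numeric(3))
    }
    total_ll <- 0; used <- 0L
    for (u in seq_along(feats)) {
      X <- feats[[u]]; seqp <- transcriptions[[u]]
      if (nrow(X) < 3L * length(seqp)) {
        warning("utterance ", u, " too short for its transcription; skipped")
        next
      }
      fb <- forward_backward(hset, X, seqp)
      if (!is.finite(fb$loglik_forward)) {
        warning("utterance ", u, " has zero probability; skipped")
        next
      }
      total_ll <- total_ll + fb$loglik_forward; used <- used + 1L
      ch <- fb$chain; T_ <- nrow(X); J <- ch$J
      la <- fb$log_alpha; lb <- fb$log_beta; logb <- fb$logb
      L <- fb$loglik_forward
      # transition occupancies along the chain
      if (T_ >= 2L) {
        t_idx <- 1:(T_ - 1)
        self_m <- exp(la[t_idx, , drop = FALSE] +
                        rep(ch$lself, each = T_ - 1) +
                        logb[t_idx + 1, , drop = FALSE] +
                        lb[t_idx + 1, , drop = FALSE] - L)
        move_m <- exp(la[t_idx, -J, drop = FALSE] +
                        rep(ch$lprev[-1], each = T_ - 1) +
                        logb[t_idx + 1, -1, drop = FALSE] +
                        lb[t_idx + 1, -1, drop = FALSE] - L)
        self_tot <- colSums(self_m)
        fwd_tot <- c(colSums(move_m), 0)       # arc leaving j recorded at j
      } else {
        self_tot <- numeric(J); fwd_tot <- numeric(J)
      }
      fwd_tot[J] <- fwd_tot[J] + 1             # mandatory exit at time T
      for (j in seq_len(J)) {
        ph <- seqp[ch$phone_of[j]]; s <- ch$state_of[j]
        acc[[ph]]$self[s] <- acc[[ph]]$self[s] + self_tot[j]
        acc[[ph]]$fwd[s] <- acc[[ph]]$fwd[s] + fwd_tot[j]
      }
      # mixture occupancies
      for (j in seq_len(J)) {
        ph <- seqp[ch$phone_of[j]]; s <- ch$state_of[j]
        g <- hset$models[[ph]]$gmms[[s]]
        cl <- gmm_state_loglik(g, X)
        gocc <- exp(la[, j] + lb[, j] - L + cl$comp - cl$state)
        gocc[!is.finite(gocc)] <- 0
        gocc <- rbind(gocc)
        if (is.null(dim(gocc))) gocc <- matrix(gocc, ncol = length(g$w))
        acc[[ph]]$occ[[s]] <- acc[[ph]]$occ[[s]] + colSums(gocc)
        acc[[ph]]$sx[[s]] <- acc[[ph]]$sx[[s]] + t(gocc) %*% X
        acc[[ph]]$sx2[[s]] <- acc[[ph]]$sx2[[s]] + t(gocc) %*% X^2
      }
    }
    if (used == 0L) stop("no usable utterance in the corpus")
    # update
    for (ph in hset$phones) {
      a <- acc[[ph]]
      m <- hset$models[[ph]]
      for (s in 1:3) {
        tot <- a$self[s] + a$fwd[s]
        if (tot > 0) {
          m$trans[s + 1, s + 1] <- a$self[s] / tot
          m$trans[s + 1, s + 2] <- a$fwd[s] / tot
        }
        occ <- a$occ[[s]]
        if (sum(occ) > 1e-8) {
          keep <- occ > 1e-8
          mu <- a$sx[[s]] / pmax(occ, 1e-300)
          vv <- a$sx2[[s]] / pmax(occ, 1e-300) - mu^2
          vv <- sweep(vv, 2, floor_v, pmax)
          m$gmms[[s]]$w[keep] <- occ[keep] / sum(occ)
          m$gmms[[s]]$w <- m$gmms[[s]]$w / sum(m$gmms[[s]]$w)
          m$gmms[[s]]$mu[keep, ] <- mu[keep, , drop = FALSE]
          m$gmms[[s]]$var[keep, ] <- vv[keep, , drop = FALSE]
        }
      }
      hset$models[[ph]] <- m
    }
    trace <- c(trace, total_ll)
  }
  attr(hset, "loglik_trace") <- trace
  hset
}

#' Split mixture components (binary splitting)
#'
#' Doubles the number of Gaussians per state towards `target_n` by
#' perturbing each component's mean by +/- 0.2 standard deviations and
#' halving its weight. When `target_n` is not a power of two away, only
#' the heaviest components are split in the final round. Callers retrain
#' with [baum_welch()] between increments.
#'
#' @param hset A `phone_hmm_set`.
#' @param target_n Desired number of Gaussians per state.
#' @return The `phone_hmm_set` with enlarged mixtures.
#' @export
split_mixtures <- function(hset, target_n) {
  if (target_n > 16L)
    warning("more than 16 Gaussians per state exceeds the intended operating range")
  split_gmm <- function(g, n_new) {
    K <- length(g$w)
    n_split <- min(K, n_new - K)
    if (n_split <= 0L) return(g)
    ord <- order(g$w, decreasing = TRUE)[seq_len(n_split)]
    for (k in ord) {
      off <- 0.2 * sqrt(g$var[k, ])
      g$mu <- rbind(g$mu, g$mu[k, ] - off)
      g$var <- rbind(g$var, g$var[k, ])
      g$w <- c(g$w, g$w[k] / 2)
      g$mu[k, ] <- g$mu[k, ] + off
      g$w[k] <- g$w[k] / 2
    }
    g$w <- g$w / sum(g$w)
    g
  }
  for (ph in hset$phones) {
    for (s in 1:3) {
      g <- hset$models[[ph]]$gmms[[s]]
      K <- length(g$w)
      if (K < target_n)
        hset$models[[ph]]$gmms[[s]] <- split_gmm(g, min(target_n, 2L * K))
    }
  }
  hset
}

#' Train a monophone recognizer with a mixture-splitting schedule
#'
#' Flat start, Baum-Welch, then successive binary splitting
#' (1 -> 2 -> 4 -> ... -> `n_mix`) with re-estimation after each split.
#'
#' @param feats List of feature matrices.
#' @param transcriptions List of phone-label vectors.
#' @param phones Phone inventory.
#' @param n_mix Final number of Gaussians per state (16 is the usual
#'   ceiling for this model family).
#' @param iters_per_stage Baum-Welch iterations per stage.
#' @param var_floor_frac Variance floor fraction.
#' @return A trained `phone_hmm_set` with attribute `loglik_trace`.
#' @export
train_recognizer <- function(feats, transcriptions, phones, n_mix = 1L,
                             iters_per_stage = 3L, var_floor_frac = 1e-2) {
  hset <- flat_start(phones, feats)
  hset <- baum_welch(hset, feats, transcriptions, iters_per_stage, var_floor_frac)
  trace <- attr(hset, "loglik_trace")
  K <- 1L
  while (K < n_mix) {
    K <- min(2L * K, n_mix)
    hset <- split_mixtures(hset, K)
    hset <- baum_welch(hset, feats, transcriptions, iters_per_stage, var_floor_frac)
    trace <- c(trace, attr(hset, "loglik_trace"))
  }
  attr(hset, "loglik_trace") <- trace
  hset
}
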