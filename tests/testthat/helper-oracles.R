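# Independent brute-force oracles used across tests. These deliberately
# re-derive results by exhaustive enumeration or closed form, never by
# calling the implementation under test.

# Minimum accumulated cost over ALL monotone warping paths, by explicit
# forward enumeration with steps (1,0), (0,1), (1,1).
bf_dtw_cost <- function(X, Y) {
  ld <- as.matrix(stats::dist(rbind(X, Y)))[seq_len(nrow(X)),
                                            nrow(X) + seq_len(nrow(Y)),
                                            drop = FALSE]
  n <- nrow(X); m <- nrow(Y)
  best <- Inf
  rec <- function(i, j, acc) {
    acc <- acc + ld[i, j]
    if (acc >= best) return(invisible())
    if (i == n && j == m) { best <<- acc; return(invisible()) }
    if (i < n && j < m) rec(i + 1, j + 1, acc)
    if (j < m) rec(i, j + 1, acc)
    if (i < n) rec(i + 1, j, acc)
    invisible()
  }
  rec(1, 1, 0)
  best
}

# Plain Levenshtein cost (unit costs) by recursion with memoization.
bf_edit_cost <- function(ref, hyp) {
  n <- length(ref); m <- length(hyp)
  memo <- matrix(NA_real_, n + 1, m + 1)
  rec <- function(i, j) {
    if (!is.na(memo[i + 1, j + 1])) return(memo[i + 1, j + 1])
    v <- if (i == 0) j else if (j == 0) i else {
      min(rec(i - 1, j - 1) + (ref[i] != hyp[j]),
          rec(i - 1, j) + 1,
          rec(i, j - 1) + 1)
    }
    memo[i + 1, j + 1] <<- v
    v
  }
  rec(n, m)
}

# Exhaustive decoding: enumerate every phone sequence and every state
# alignment through the concatenated 3-emitting-state chains; returns
# the best sequence and its joint log score under the same scoring rule
# as the decoder (bigram-scaled LM, per-phone insertion penalty).
bf_decode <- function(hset, X, lm = NULL, lm_scale = 1, ins_penalty = 0) {
  T_ <- nrow(X); P <- length(hset$phones)
  best <- -Inf; best_seq <- NULL
  state_ll <- function(ph, s, t) {
    g <- hset$models[[ph]]$gmms[[s]]
    ll <- vapply(seq_along(g$w), function(k)
      log(g$w[k]) + sum(stats::dnorm(X[t, ], g$mu[k, ], sqrt(g$var[k, ]),
                                     log = TRUE)), numeric(1))
    m <- max(ll); m + log(sum(exp(ll - m)))
  }
  score_alignment <- function(seqp, breaks) {
    # breaks: frame counts per emitting state (length 3 * length(seqp))
    tot <- 0; t <- 0L
    for (u in seq_along(breaks)) {
      ph <- seqp[ceiling(u / 3)]; s <- (u - 1L) %% 3L + 1L
      tr <- hset$models[[ph]]$trans
      d <- breaks[u]
      for (r in seq_len(d)) tot <- tot + state_ll(ph, s, t + r)
      tot <- tot + (d - 1) * log(tr[s + 1, s + 1]) + log(tr[s + 1, s + 2])
      t <- t + d
    }
    tot
  }
  lm_score <- function(seqp) {
    if (is.null(lm)) return(length(seqp) * ins_penalty)
    li <- match(seqp, lm$phones)
    sc <- unname(lm$logp_start[li[1]])
    if (length(seqp) >= 2)
      for (i in 2:length(seqp)) sc <- sc + lm$logp[li[i - 1], li[i]]
    lm_scale * sc + length(seqp) * ins_penalty
  }
  compositions <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    out <- NULL
    for (first in seq_len(total - parts + 1))
      out <- rbind(out, cbind(first, compositions(total - first, parts - 1)))
    out
  }
  for (L in seq_len(T_ %/% 3)) {
    seqs <- as.matrix(expand.grid(rep(list(seq_len(P)), L)))
    comps <- compositions(T_, 3L * L)
    for (r in seq_len(nrow(seqs))) {
      seqp <- hset$phones[seqs[r, ]]
      base <- lm_score(seqp)
      for (cc in seq_len(nrow(comps))) {
        sc <- base + score_alignment(seqp, comps[cc, ])
        if (sc > best) { best <- sc; best_seq <- seqp }
      }
    }
  }
  list(seq = unname(best_seq), logprob = unname(best))
}

# Multivariate OLS oracle: y ~ x with intercept via lm.fit.
bf_ols_predict <- function(X, Y, Xnew) {
  fit <- stats::lm.fit(cbind(1, X), Y)
  cbind(1, Xnew) %*% fit$coefficients
}

# Small parallel feature corpus for conversion tests: target drawn from a
# speaker model, source a fixed affine map of it plus optional noise.
make_affine_pair_corpus <- function(n_sentences, seed, noise_sd = 0,
                                    K = 5, dim = 4, warp = 1) {
  mod <- make_speaker(K = K, dim = dim, seed = seed, spread = 2)
  spec <- distortion_spec(dim = dim, seed = seed + 1, noise_sd = noise_sd,
                          warp = warp, jitter_sd = 0)
  tgt <- lapply(seq_len(n_sentences), function(s)
    sample_utterance(mod, n_phones = 5, seed = seed + 10 + s))
  src <- lapply(seq_along(tgt), function(s)
    distort(tgt[[s]], spec, seed = seed + 100 + s))
  list(src = lapply(src, `[[`, "features"),
       tgt = lapply(tgt, `[[`, "features"),
       spec = spec, model = mod)
}
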