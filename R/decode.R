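# Phone decoding: bigram language model over the phone inventory and
# Viterbi token passing through the phone-loop network.

#' Train a bigram phone language model
#'
#' Maximum-likelihood bigram counts over successive phones in the
#' training transcriptions with add-k smoothing over the inventory.
#' The model holds `P(phone | previous phone)` and the sentence-initial
#' distribution; utterance end is handled by the acoustic models' exit
#' transitions, not the language model.
#'
#' @param transcriptions List of phone-label vectors.
#' @param phones Phone inventory (defaults to labels seen in the data).
#' @param k Add-k smoothing constant (0 = pure relative frequencies).
#' @return An object of class `bigram_lm` with `logp` (rows = history,
#'   columns = next phone) and `logp_start`.
#' @export
train_bigram <- function(transcriptions, phones = NULL, k = 1) {
  if (length(transcriptions) < 1L) stop("at least one transcription is required")
  if (is.null(phones)) phones <- sort(unique(unlist(transcriptions)))
  unknown <- setdiff(unique(unlist(transcriptions)), phones)
  if (length(unknown) > 0L)
    stop("unknown phone label(s): ", paste(unknown, collapse = ", "))
  V <- length(phones)
  counts <- matrix(0, V, V, dimnames = list(phones, phones))
  start <- stats::setNames(numeric(V), phones)
  for (tr in transcriptions) {
    if (length(tr) == 0L) next
    start[tr[1]] <- start[tr[1]] + 1
    if (length(tr) >= 2L)
      for (i in seq_len(length(tr) - 1L))
        counts[tr[i], tr[i + 1L]] <- counts[tr[i], tr[i + 1L]] + 1
  }
  p <- (counts + k) / (rowSums(counts) + k * V)
  ps <- (start + k) / (sum(start) + k * V)
  if (k == 0) {                       # leave unseen rows uniform, not NaN
    bad <- rowSums(counts) == 0
    p[bad, ] <- 1 / V
    if (sum(start) == 0) ps[] <- 1 / V
  }
  structure(list(phones = phones, logp = log(p), logp_start = log(ps), k = k),
            class = "bigram_lm")
}

#' @export
print.bigram_lm <- function(x, ...) {
  cat(sprintf("<bigram_lm: %d phones, add-%g smoothing>\n",
              length(x$phones), x$k))
  invisible(x)
}

#' Viterbi phone decoding through the bigram-weighted phone loop
#'
#' Finds the best phone sequence for a feature stream by token passing
#' through the network in which every phone HMM can follow every other,
#' with the arc between two phones weighted by
#' `lm_scale * log P(next | prev) + ins_penalty`. With `lm_scale = 0`
#' and `ins_penalty = 0` decoding depends on the acoustics alone.
#' Deterministic: ties resolve to the first (lowest-index) candidate.
#'
#' @param hset A trained `phone_hmm_set`.
#' @param X Feature matrix of the utterance; 0 rows gives an empty result.
#' @param lm Optional `bigram_lm` over (a superset of) the same phones.
#' @param lm_scale Language-model log-probability scale.
#' @param ins_penalty Additive log-domain penalty per phone entered.
#' @return Character vector: the decoded phone string.
#' @export
viterbi_decode <- function(hset, X, lm = NULL, lm_scale = 1, ins_penalty = 0) {
  if (is.null(dim(X))) X <- rbind(X)
  if (nrow(X) == 0L) return(character(0))
  stopifnot_matrix(X)
  if (ncol(X) != hset$dim)
    stop("feature dimension ", ncol(X), " does not match models (", hset$dim, ")")
  P <- length(hset$phones)
  if (!is.null(lm)) {
    if (!all(hset$phones %in% lm$phones))
      stop("language model does not cover the phone inventory")
    li <- match(hset$phones, lm$phones)
    lm_mat <- lm$logp[li, li, drop = FALSE] * lm_scale
    lm_start <- lm$logp_start[li] * lm_scale
  } else {
    lm_mat <- matrix(0, P, P)
    lm_start <- numeric(P)
  }
  T_ <- nrow(X)
  B <- emission_logliks(hset, X)               # T x 3P
  tr <- vapply(hset$phones, function(ph) {
    tt <- hset$models[[ph]]$trans
    log(c(tt[2, 2], tt[2, 3], tt[3, 3], tt[3, 4], tt[4, 4], tt[4, 5]))
  }, numeric(6))                               # 6 x P
  s1 <- seq(1L, 3L * P, by = 3L); s2 <- s1 + 1L; s3 <- s1 + 2L
  lself <- numeric(3L * P); lfwd <- numeric(3L * P)
  lself[s1] <- tr[1, ]; lself[s2] <- tr[3, ]; lself[s3] <- tr[5, ]
  lfwd[s2] <- tr[2, ]; lfwd[s3] <- tr[4, ]
  lexit <- tr[6, ]

  NBIG <- 3L * P
  delta <- rep(-Inf, NBIG)
  delta[s1] <- lm_start + ins_penalty + B[1, s1]
  psi <- matrix(0L, T_, NBIG)                  # 0=start, j=prev state, NBIG+q=entry from q
  if (T_ >= 2L) {
    for (t in 2:T_) {
      exit_sc <- delta[s3] + lexit
      # best predecessor phone for each next phone
      cand <- exit_sc + lm_mat                 # P x P: rows = prev, cols = next
      best_q <- max.col(t(cand), ties.method = "first")
      entry <- cand[cbind(best_q, seq_len(P))] + ins_penalty
      nd <- rep(-Inf, NBIG); np <- integer(NBIG)
      stay <- delta + lself
      # state 1: stay vs fresh entry
      use_entry <- entry > stay[s1]
      nd[s1] <- ifelse(use_entry, entry, stay[s1])
      np[s1] <- ifelse(use_entry, NBIG + best_q, s1)
      # states 2 and 3: stay vs forward from previous state
      mv2 <- delta[s1] + lfwd[s2]
      use2 <- mv2 > stay[s2]
      nd[s2] <- ifelse(use2, mv2, stay[s2]); np[s2] <- ifelse(use2, s1, s2)
      mv3 <- delta[s2] + lfwd[s3]
      use3 <- mv3 > stay[s3]
      nd[s3] <- ifelse(use3, mv3, stay[s3]); np[s3] <- ifelse(use3, s2, s3)
      delta <- nd + B[t, ]
      psi[t, ] <- np
    }
  }
  final <- delta[s3] + lexit
  if (all(!is.finite(final))) stop("no admissible decoding path")
  p_best <- which.max(final)
  # backtrace, recording a phone at each entry event
  out <- character(0)
  j <- s3[p_best]
  t <- T_
  while (t >= 1L) {
    if (t == 1L) {
      out <- c(((j - 1L) %/% 3L) + 1L, out)
      break
    }
    prev <- psi[t, j]
    if (prev > NBIG) {                         # entered this phone at time t
      out <- c(((j - 1L) %/% 3L) + 1L, out)
      j <- s3[prev - NBIG]
      t <- t - 1L
    } else {
      j <- prev
      t <- t - 1L
    }
  }
  res <- hset$phones[as.integer(out)]
  attr(res, "logprob") <- max(final)
  res
}
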