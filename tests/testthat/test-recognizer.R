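make_toy_corpus <- function(K = 3, dim = 4, n_train = 10, seed = 1,
                            spread = 4) {
  mod <- make_speaker(K = K, dim = dim, seed = seed, spread = spread)
  utts <- lapply(seq_len(n_train), function(s)
    sample_utterance(mod, n_phones = 4, seed = seed + s))
  list(model = mod,
       feats = lapply(utts, `[[`, "features"),
       trans = lapply(utts, `[[`, "phone_seq"))
}

test_that("flat start ties all states to the global Gaussian", {
  tc <- make_toy_corpus(seed = 41)
  h <- flat_start(tc$model$phones, tc$feats)
  X <- do.call(rbind, tc$feats)
  g11 <- h$models[[1]]$gmms[[1]]
  expect_equal(drop(g11$mu), colMeans(X))
  expect_identical(ncol(g11$mu), 4L)
  for (ph in h$phones)
    for (s in 1:3)
      expect_identical(h$models[[ph]]$gmms[[s]], g11)
  for (ph in h$phones)
    expect_equal(rowSums(h$models[[ph]]$trans)[1:4], rep(1, 4),
                 ignore_attr = TRUE)
  expect_error(flat_start(tc$model$phones, list()), "empty corpus")
})

test_that("forward and backward total likelihoods agree", {
  tc <- make_toy_corpus(seed = 42)
  h <- flat_start(tc$model$phones, tc$feats)
  h <- baum_welch(h, tc$feats, tc$trans, n_iter = 2)
  for (u in 1:3) {
    fb <- forward_backward(h, tc$feats[[u]], tc$trans[[u]])
    expect_equal(fb$loglik_forward, fb$loglik_backward, tolerance = 1e-8)
    # state posteriors sum to one at every frame
    expect_equal(rowSums(fb$gamma), rep(1, nrow(tc$feats[[u]])),
                 tolerance = 1e-8)
  }
})

test_that("Baum-Welch log-likelihood is non-decreasing", {
  tc <- make_toy_corpus(seed = 43)
  h <- flat_start(tc$model$phones, tc$feats)
  h <- baum_welch(h, tc$feats, tc$trans, n_iter = 8)
  tr <- attr(h, "loglik_trace")
  expect_identical(length(tr), 8L)
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
})

test_that("re-estimation on stationary data preserves the pooled mean exactly", {
  set.seed(44)
  X <- matrix(rnorm(240 * 3, mean = 2), 240)
  h <- flat_start("a", list(X))
  h20 <- baum_welch(h, list(X), list("a"), n_iter = 20)
  # hand-rolled single update from the current posteriors must match the
  # occupancy identity: occupancy-weighted state means pool to the
  # sample mean because per-frame posteriors sum to 1
  fb <- forward_backward(h20, X, "a")
  occ <- colSums(fb$gamma)
  mus <- t(fb$gamma) %*% X / occ
  pooled <- colSums(mus * occ) / sum(occ)
  expect_equal(pooled, colMeans(X), tolerance = 1e-10)
  # and each trained state mean sits near the generating mean
  for (s in 1:3)
    expect_lt(max(abs(h20$models[["a"]]$gmms[[s]]$mu - 2)), 0.5)
})

test_that("mixture splitting doubles components and keeps weights normalized", {
  tc <- make_toy_corpus(seed = 45)
  h <- flat_start(tc$model$phones, tc$feats)
  h <- baum_welch(h, tc$feats, tc$trans, n_iter = 3)
  ll_before <- utils::tail(attr(h, "loglik_trace"), 1)
  rounds <- 0L
  target <- 16L
  hh <- h
  while (max(lengths(lapply(hh$models[[1]]$gmms, `[[`, "w"))) < target) {
    hh <- split_mixtures(hh, min(2L * length(hh$models[[1]]$gmms[[1]]$w), target))
    rounds <- rounds + 1L
  }
  expect_identical(rounds, 4L)          # 1 -> 2 -> 4 -> 8 -> 16
  for (ph in hh$phones)
    for (s in 1:3)
      expect_equal(sum(hh$models[[ph]]$gmms[[s]]$w), 1)
  # one split round plus retraining does not lose likelihood
  h2 <- split_mixtures(h, 2L)
  h2 <- baum_welch(h2, tc$feats, tc$trans, n_iter = 3)
  ll_after <- utils::tail(attr(h2, "loglik_trace"), 1)
  expect_gte(ll_after, ll_before - 1e-6 * abs(ll_before))
  expect_warning(split_mixtures(h, 32L), "16 Gaussians")
})

test_that("bigram estimates match add-k count arithmetic", {
  phones <- sampa_phones()             # 36 labels
  lm <- train_bigram(list(c("a", "b", "a", "b")), phones, k = 1)
  expect_equal(exp(lm$logp["a", "b"]), (2 + 1) / (2 + 36))
  expect_equal(rowSums(exp(lm$logp)), rep(1, 36), tolerance = 1e-12,
               ignore_attr = TRUE)
  # k = 0 on a covering corpus gives pure relative frequencies
  lm0 <- train_bigram(list(c("a", "b", "a", "b", "a")), c("a", "b"), k = 0)
  expect_equal(exp(lm0$logp["a", "b"]), 1)
  expect_equal(exp(lm0$logp["b", "a"]), 1)
  expect_error(train_bigram(list(c("a", "q!")), c("a", "b")), "unknown phone")
})

test_that("Viterbi equals exhaustive enumeration on toy problems", {
  tc <- make_toy_corpus(K = 3, dim = 2, seed = 46, spread = 3)
  h <- flat_start(tc$model$phones, tc$feats)
  h <- baum_welch(h, tc$feats, tc$trans, n_iter = 4)
  lm <- train_bigram(tc$trans, tc$model$phones, k = 1)
  set.seed(47)
  for (r in 1:6) {
    T_ <- sample(3:6, 1)
    X <- matrix(rnorm(T_ * 2, mean = sample(c(-2, 2), 1)), T_)
    for (args in list(list(lm = NULL, lm_scale = 0, ins_penalty = 0),
                      list(lm = lm, lm_scale = 1, ins_penalty = -0.5))) {
      got <- viterbi_decode(h, X, args$lm, args$lm_scale, args$ins_penalty)
      want <- bf_decode(h, X, args$lm, args$lm_scale, args$ins_penalty)
      expect_identical(as.character(got), want$seq)
      expect_equal(attr(got, "logprob"), want$logprob, tolerance = 1e-8)
    }
  }
  expect_identical(viterbi_decode(h, matrix(0, 0, 2), lm), character(0))
})

test_that("decoding is acoustically driven when the LM scale is zero", {
  tc <- make_toy_corpus(K = 2, dim = 3, seed = 48, spread = 10)
  h <- flat_start(tc$model$phones, tc$feats)
  h <- baum_welch(h, tc$feats, tc$trans, n_iter = 4)
  # frames drawn far inside phone A's emission decode as pure A
  phA <- tc$model$phones[1]
  XA <- matrix(rep(tc$model$means[phA, ], each = 12), 12) +
    matrix(rnorm(36, sd = 0.05), 12)
  out <- viterbi_decode(h, XA, lm = NULL, lm_scale = 0)
  expect_true(all(out == phA))
})

test_that("training and decoding well-separated phones is near-perfect", {
  tc <- make_toy_corpus(K = 4, dim = 6, n_train = 15, seed = 49, spread = 5)
  h <- train_recognizer(tc$feats, tc$trans, tc$model$phones, n_mix = 2,
                        iters_per_stage = 3)
  lm <- train_bigram(tc$trans, tc$model$phones)
  test <- lapply(1:8, function(s)
    sample_utterance(tc$model, n_phones = 5, seed = 900 + s))
  sc <- score_corpus(lapply(test, `[[`, "phone_seq"),
                     lapply(test, function(u) viterbi_decode(h, u$features, lm)))
  expect_gt(sc$accuracy, 90)
})
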