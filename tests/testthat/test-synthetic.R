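test_that("speaker models are reproducible with guaranteed separation", {
  m1 <- make_speaker(K = 5, dim = 4, seed = 77)
  m2 <- make_speaker(K = 5, dim = 4, seed = 77)
  expect_identical(m1, m2)
  m3 <- make_speaker(K = 8, dim = 4, seed = 78, min_separation = 6)
  expect_gte(min(dist(m3$means)), 6)
  m36 <- make_speaker(K = 36, seed = 79)
  expect_identical(m36$phones, sampa_phones())
  expect_identical(m36$K, 36L)
  expect_error(make_speaker(K = 1), "at least two")
})

test_that("utterance sampling honours durations and transcription units", {
  mod <- make_speaker(K = 4, dim = 3, seed = 80)
  u <- sample_utterance(mod, phone_seq = c("p", "b"), durations = c(10L, 12L))
  expect_identical(nrow(u$features), 22L)
  expect_identical(nrow(u$transcription), 2L)
  expect_identical(u$transcription$start, c(0L, 1600L))
  expect_identical(u$transcription$end, c(1600L, 3520L))
  expect_error(sample_utterance(mod, phone_seq = character(0)), "empty phone")
  # reproducibility
  a <- sample_utterance(mod, n_phones = 5, seed = 3)
  b <- sample_utterance(mod, n_phones = 5, seed = 3)
  expect_identical(a, b)
  # long-run per-phone sample mean near the model mean
  big <- sample_utterance(mod, phone_seq = "p", durations = 10000L, seed = 4)
  se <- sqrt(mod$vars["p", ]) / 100
  expect_true(all(abs(colMeans(big$features) - mod$means["p", ]) < 3 * se))
})

test_that("identity distortion is a no-op and warping rescales durations", {
  mod <- make_speaker(K = 3, dim = 3, seed = 81)
  u <- sample_utterance(mod, n_phones = 4, seed = 5)
  ident <- distortion_spec(dim = 3, A = diag(3), b = rep(0, 3),
                           noise_sd = 0, warp = 1, jitter_sd = 0)
  expect_equal(distort(u, ident, seed = 1)$features, u$features)
  doubled <- distortion_spec(dim = 3, A = diag(3), b = rep(0, 3),
                             noise_sd = 0, warp = 2, jitter_sd = 0)
  v <- distort(u, doubled, seed = 1)
  d_old <- diff(c(0, u$transcription$end)) / 160
  d_new <- diff(c(0, v$transcription$end)) / 160
  expect_true(all(abs(d_new - 2 * d_old) <= 1))
  expect_error(distortion_spec(warp = 0), "positive")
})

test_that("a noiseless affine distortion is recovered by G=1 conversion", {
  mod <- make_speaker(K = 4, dim = 3, seed = 82)
  spec <- distortion_spec(dim = 3, seed = 83, noise_sd = 0, warp = 1,
                          jitter_sd = 0)
  u <- sample_utterance(mod, n_phones = 6, seed = 6)
  v <- distort(u, spec, seed = 2)
  # source = A y + b exactly, so the G=1 backward regression reproduces y
  Z <- cbind(v$features, u$features)
  fn <- conversion_function(estimate_joint_gmm(Z, rep(1L, nrow(Z)), dx = 3L))
  expect_lt(max(abs(convert(fn, v$features) - u$features)), 1e-6)
})

test_that("parallel corpora share content, split cleanly and stay reproducible", {
  mod <- make_speaker(K = 6, dim = 3, seed = 84)
  spec <- distortion_spec(dim = 3, seed = 85)
  cp <- generate_parallel_corpus(50, mod, spec, seed = 86)
  expect_identical(length(cp$source), 50L)
  expect_identical(length(cp$target), 50L)
  for (s in c(1, 25, 50))
    expect_identical(cp$source[[s]]$phone_seq, cp$target[[s]]$phone_seq)
  cp2 <- generate_parallel_corpus(50, mod, spec, seed = 86)
  expect_equal(cp, cp2)
  # the full-size 425/55 split is reproducible and disjoint
  big <- generate_parallel_corpus(480, mod, spec, seed = 87,
                                  train_frac = 425 / 480)
  expect_identical(sum(big$split == "train"), 425L)
  expect_identical(sum(big$split == "test"), 55L)
  expect_identical(intersect(which(big$split == "train"),
                             which(big$split == "test")), integer(0))
})
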