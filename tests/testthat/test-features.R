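test_that("pre-emphasis implements the HTK first-difference filter", {
  expect_equal(preemphasize(c(1, 1, 1, 1), 0.97)$samples, c(1, 0.03, 0.03, 0.03))
  expect_equal(preemphasize(c(0, 1, 0, 0), 0.97)$samples, c(0, 1, -0.97, 0))
  s <- rnorm(100)
  expect_equal(preemphasize(s, 0)$samples, s)
  expect_error(preemphasize(numeric(0)), "no audio")
  expect_error(preemphasize(s, 1), "\\[0, 1\\)")
})

test_that("frame count matches brute-force window enumeration", {
  expect_identical(n_frames(16000), 98L)
  cfg <- frame_config()
  for (len in c(399, 400, 401, 560, 561, 7919, 16000, 16159, 16160)) {
    starts <- seq(0, len, by = 160)
    bf <- sum(starts + 400 <= len)
    expect_identical(n_frames(len, 16000, cfg), as.integer(bf))
  }
  expect_error(extract_static(rnorm(399)), "shorter than one analysis window")
})

test_that("silence with dither gives stationary cepstra and energy at the ceiling", {
  set.seed(42)
  w <- waveform(rnorm(8000, sd = 1e-4))
  X <- extract_static(w)
  expect_identical(ncol(X), 13L)
  expect_lt(max(apply(X[, 1:12], 2, sd)), 1)   # near-constant cepstra
  expect_equal(max(X[, 13]), 0)                # max-normalized log energy
})

test_that("energy normalization cancels a global gain factor", {
  set.seed(1)
  s <- rnorm(6400) * seq(0.5, 2, length.out = 6400)
  e1 <- extract_static(waveform(s))[, 13]
  e2 <- extract_static(waveform(100 * s))[, 13]
  expect_equal(e1, e2, tolerance = 1e-10)
})

test_that("delta reproduces the five-frame regression formula", {
  const <- matrix(5, 20, 3)
  expect_equal(delta(const), matrix(0, 20, 3))
  # linear ramp of slope s: interior delta equals s
  s <- 0.7
  ramp <- matrix(rep(s * (1:30), 2), 30)
  d <- delta(ramp, 2)
  expect_equal(d[3:28, ], matrix(s, 26, 2))
  # isolated unit pulse at the center frame has zero delta there
  pulse <- matrix(c(0, 0, 1, 0, 0), 5, 1)
  expect_equal(delta(pulse, 2)[3, 1], 0)
  expect_warning(delta(matrix(1, 3, 1), 2), "edge replication")
})

test_that("delta is linear on interior frames", {
  set.seed(3)
  X <- matrix(rnorm(60), 20); Y <- matrix(rnorm(60), 20)
  a <- 2.5; b <- -0.3
  lhs <- delta(a * X + b * Y)
  rhs <- a * delta(X) + b * delta(Y)
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("derivative stacking yields 39- and 52-dim vectors consistently", {
  set.seed(4)
  X <- matrix(rnorm(25 * 13), 25)
  s2 <- stack_derivatives(X, 2)
  s3 <- stack_derivatives(X, 3)
  expect_identical(ncol(s2), 39L)
  expect_identical(ncol(s3), 52L)
  expect_equal(unname(s3[, 1:39]), unname(s2))
  const <- matrix(1, 25, 13)
  expect_equal(unname(stack_derivatives(const, 3)[, 14:52]), matrix(0, 25, 39))
  expect_error(stack_derivatives(X[, 1:12], 2), "13 columns")
  expect_error(stack_derivatives(X, 4), "order")
})

test_that("the MFCC front-end processes synthesized audio end to end", {
  w <- synthesize_waveform(c("a", "s"), c(20, 20), seed = 9)
  X <- extract_static(w)
  expect_identical(nrow(X), n_frames(length(w)))
  expect_true(all(is.finite(X)))
  # the two phones have different spectra, so cepstra differ between halves
  expect_gt(sum(abs(colMeans(X[1:15, 1:12]) - colMeans(X[22:36, 1:12]))), 0.5)
})
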