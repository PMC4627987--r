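test_that("class statistics match hand-computed moments", {
  X <- matrix(c(0, 0, 2, 0, 1, 3, 3, 3), 4, 2, byrow = TRUE)
  lab <- c("a", "a", "b", "b")
  st <- accumulate_stats(X, lab)
  expect_equal(unname(st$means["a", ]), c(1, 0))
  expect_equal(unname(st$means["b", ]), c(2, 3))
  expect_equal(st$covs[, , "a"], matrix(c(1, 0, 0, 0), 2))
  expect_equal(st$covs[, , "b"], matrix(c(1, 0, 0, 0), 2))
  expect_equal(unname(st$counts), c(2, 2))
  expect_equal(st$mean, colMeans(X))
  expect_error(accumulate_stats(X, rep("a", 4)), "2 classes")
  # identical per-class data makes class stats equal global stats
  Y <- rbind(X, X)
  st2 <- accumulate_stats(Y, rep(c("a", "b"), each = 4))
  expect_equal(st2$covs[, , "a"], st2$cov)
  expect_equal(unname(st2$means["a", ]), st2$mean)
})

test_that("the objective from sufficient statistics equals per-frame evaluation", {
  set.seed(31)
  X <- rbind(matrix(rnorm(200, -2), 100, 2), matrix(rnorm(200, 2), 100, 2))
  lab <- rep(c("a", "b"), each = 100)
  st <- accumulate_stats(X, lab)
  h <- estimate_hlda(st, p = 1)
  # brute force: evaluate the model density frame by frame with the
  # ML-imputed diagonal variances in the projected space
  Theta <- h$Theta; p <- h$p
  proj <- X %*% t(Theta)
  ldet <- as.numeric(determinant(Theta, logarithm = TRUE)$modulus)
  bf <- 0
  for (i in seq_len(nrow(X))) {
    for (j in 1:2) {
      if (j <= p) {
        sel <- lab == lab[i]
        m <- mean(proj[sel, j]); v <- mean((proj[sel, j] - m)^2)
      } else {
        m <- mean(proj[, j]); v <- mean((proj[, j] - m)^2)
      }
      bf <- bf - 0.5 * (log(2 * pi) + log(v) + (proj[i, j] - m)^2 / v)
    }
    bf <- bf + ldet
  }
  expect_equal(hlda_loglik(h, st), bf, tolerance = 1e-8)
  # label order must not matter
  st_perm <- accumulate_stats(X[200:1, ], lab[200:1])
  expect_equal(hlda_loglik(h, st_perm), hlda_loglik(h, st), tolerance = 1e-10)
})

test_that("row updates never decrease the objective and find the true axis", {
  set.seed(32)
  n <- 2500
  X <- rbind(cbind(rnorm(n, -5), rnorm(n)), cbind(rnorm(n, 5), rnorm(n)))
  lab <- rep(c("a", "b"), each = n)
  st <- accumulate_stats(X, lab)
  h <- estimate_hlda(st, p = 1)
  expect_true(all(diff(h$trace) >= -1e-8))
  r1 <- h$Theta[1, ] / sqrt(sum(h$Theta[1, ]^2))
  expect_gt(abs(r1[1]), 0.99)
})

test_that("HLDA separates classes that differ only in variance", {
  set.seed(33)
  n <- 3000
  X <- rbind(cbind(rnorm(n, 0, 3), rnorm(n)), cbind(rnorm(n, 0, 0.5), rnorm(n)))
  lab <- rep(c("wide", "narrow"), each = n)
  st <- accumulate_stats(X, lab)
  h <- estimate_hlda(st, p = 1)
  r1 <- h$Theta[1, ] / sqrt(sum(h$Theta[1, ]^2))
  expect_gt(abs(r1[1]), 0.99)  # LDA is indifferent here (equal means)
})

test_that("p = n is a saturated bijection and projection matches a direct product", {
  set.seed(34)
  X <- rbind(matrix(rnorm(300, -1), 150, 2), matrix(rnorm(300, 1), 150, 2))
  lab <- rep(c("a", "b"), each = 150)
  st <- accumulate_stats(X, lab)
  h <- estimate_hlda(st, p = 2, n_iters = 50)
  expect_gt(abs(det(h$Theta)), 1e-8)
  expect_identical(ncol(hlda_project(h, X)), 2L)
  # projection is just Theta_p x
  v <- rnorm(2)
  expect_equal(unname(hlda_project(h, v)), drop(h$Theta[1:2, ] %*% v),
               tolerance = 1e-12)
  expect_equal(hlda_project(h, rep(0, 2)), c(h1 = 0, h2 = 0))
  expect_error(hlda_project(h, rnorm(3)), "columns")
})

test_that("perturbing a converged transform lowers the likelihood", {
  set.seed(35)
  X <- rbind(matrix(rnorm(400, -3), 200, 2), matrix(rnorm(400, 3), 200, 2))
  lab <- rep(c("a", "b"), each = 200)
  st <- accumulate_stats(X, lab)
  h <- estimate_hlda(st, p = 1)
  ll_opt <- hlda_loglik(h, st)
  worse <- 0L
  for (r in 1:20) {
    R <- matrix(rnorm(4), 2)
    while (abs(det(R)) < 1e-3) R <- matrix(rnorm(4), 2)
    if (hlda_loglik(R, st, p = 1) < ll_opt - 1e-9) worse <- worse + 1L
  }
  expect_gte(worse, 19L)
})
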