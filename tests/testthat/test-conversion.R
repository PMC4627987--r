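test_that("k-means init partitions deterministically with live classes", {
  set.seed(10)
  Z <- matrix(rnorm(200 * 4), 200)
  one <- kmeans_init(Z, 1, seed = 3)
  expect_true(all(one$assignment == 1L))
  expect_equal(drop(one$centroids), colMeans(Z))
  # two well-separated clouds recover the separating partition
  Z2 <- rbind(matrix(rnorm(150, sd = 0.1), 50), matrix(rnorm(150, 20, 0.1), 50))
  km <- kmeans_init(Z2, 2, seed = 4)
  expect_identical(length(unique(km$assignment[1:50])), 1L)
  expect_identical(length(unique(km$assignment[51:100])), 1L)
  expect_false(km$assignment[1] == km$assignment[51])
  # determinism under a fixed seed
  km_a <- kmeans_init(Z, 8, seed = 11)
  km_b <- kmeans_init(Z, 8, seed = 11)
  expect_identical(km_a, km_b)
  expect_true(all(tabulate(km_a$assignment, 8) > 0))
  expect_error(kmeans_init(Z, 0), "between 1")
  expect_error(kmeans_init(Z, 201), "between 1")
})

test_that("joint-GMM moments match hand-computed values", {
  # two scalar pairs [0|0] and [2|2]: population moments are all 1
  Z <- matrix(c(0, 0, 2, 2), 2, byrow = TRUE)
  g <- estimate_joint_gmm(Z, c(1L, 1L), dx = 1L)
  expect_equal(g$alpha, 1)
  expect_equal(drop(g$mu), c(1, 1))
  expect_equal(g$Sigma[1, 1, 1], 1)   # source variance
  expect_equal(g$Sigma[2, 2, 1], 1)   # target variance
  expect_equal(g$Sigma[1, 2, 1], 1)   # cross covariance
  # class weights are occupancy ratios
  set.seed(12)
  Z2 <- matrix(rnorm(100 * 2), 100)
  g2 <- estimate_joint_gmm(Z2, rep(c(1L, 2L), c(30, 70)), dx = 1L)
  expect_equal(g2$alpha, c(0.3, 0.7))
  expect_equal(sum(g2$alpha), 1)
})

test_that("posteriors are normalized and concentrate with separation", {
  set.seed(13)
  Z <- rbind(matrix(rnorm(200, 0, 1), 100), matrix(rnorm(200, 10, 1), 100))
  g <- estimate_joint_gmm(Z, rep(1:2, each = 100), dx = 1L)
  P <- gmm_posterior(g, matrix(seq(-2, 12, length.out = 50), 50))
  expect_equal(rowSums(P), rep(1, 50), tolerance = 1e-12)
  expect_gt(gmm_posterior(g, g$mu[1, 1, drop = FALSE])[1, 1], 1 - 1e-8)
  one <- estimate_joint_gmm(Z, rep(1L, 200), dx = 1L)
  expect_equal(drop(gmm_posterior(one, matrix(3.3))), 1)
  expect_error(gmm_posterior(g, matrix(NaN)), "non-finite")
})

test_that("G=1 conversion equals the multivariate OLS regression", {
  set.seed(14)
  A <- matrix(rnorm(16), 4); b <- rnorm(4)
  X <- matrix(rnorm(300 * 4), 300)
  Y <- X %*% t(A) + rep(b, each = 300)
  g <- estimate_joint_gmm(cbind(X, Y), rep(1L, 300), dx = 4L)
  fn <- conversion_function(g)
  expect_lt(max(abs(convert(fn, X) - Y)), 1e-8)
  expect_lt(max(abs(convert(fn, X) - bf_ols_predict(X, Y, X))), 1e-8)
  # at the component mean the conversion returns the target mean
  expect_equal(convert(fn, g$mu[1, 1:4]), g$mu[1, 5:8], tolerance = 1e-10)
})

test_that("training on an identity corpus recovers the identity map", {
  set.seed(15)
  feats <- lapply(1:4, function(s) matrix(rnorm(40 * 3, sd = 2), 40))
  fn <- train_conversion(feats, feats, G = 3, n_outer = 1, seed = 5)
  X <- do.call(rbind, feats)
  expect_lt(max(abs(convert(fn, X) - X)), 1e-6)
})

test_that("parameters of a known joint mixture are recovered", {
  set.seed(16)
  G <- 4; n <- 10000; d <- 2          # joint dim 2 (scalar source/target)
  alpha <- c(0.1, 0.2, 0.3, 0.4)
  mu <- matrix(c(0, 0, 8, 8, 0, 8, 8, 0), G, d, byrow = TRUE)
  comp <- sample.int(G, n, replace = TRUE, prob = alpha)
  Z <- mu[comp, ] + matrix(rnorm(n * d, sd = 0.7), n)
  g <- estimate_joint_gmm(Z, comp, dx = 1L)
  expect_true(all(abs(g$alpha - alpha) < 0.02))
  for (k in 1:G) {
    se <- 0.7 / sqrt(sum(comp == k))
    expect_true(all(abs(g$mu[k, ] - mu[k, ]) < 3 * se + 1e-12))
  }
})

test_that("iterative re-alignment reduces conversion error on distorted data", {
  cp <- make_affine_pair_corpus(8, seed = 21, noise_sd = 0.3, warp = 1.3)
  fn <- train_conversion(cp$src, cp$tgt, G = 8, n_outer = 3, seed = 7)
  tr <- attr(fn, "trace")
  expect_gte(nrow(tr), 2)
  expect_lt(tr$mse[nrow(tr)], tr$mse[1])
  # single outer iteration equals plain joint-GMM training
  fn1 <- train_conversion(cp$src, cp$tgt, G = 8, n_outer = 1, seed = 7)
  expect_identical(nrow(attr(fn1, "trace")), 1L)
  expect_error(train_conversion(cp$src[1:3], cp$tgt, G = 2), "not parallel")
})
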