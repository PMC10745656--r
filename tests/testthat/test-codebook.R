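test_that("K = 1 EM lands on the closed-form Gaussian fit", {
  set.seed(2)
  X <- matrix(rnorm(400), 100, 4)
  m <- gmm_fit(X, 1, ridge = 1e-6, seed = 3)
  expect_equal(m$weights, 1, tolerance = 1e-12)
  expect_equal(m$means[1, ], colMeans(X), tolerance = 1e-10)
  # the EM fixed point is the maximum-likelihood (1/n) covariance
  n <- nrow(X)
  expect_equal(m$covs[[1]], cov(X) * (n - 1) / n + 1e-6 * diag(4),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("EM recovers two well-separated spherical clusters", {
  X <- with_seed_test(31, rbind(
    matrix(rnorm(2000, -5, 0.5), 1000, 2),
    matrix(rnorm(2000, 5, 0.5), 1000, 2)))
  m <- gmm_fit(X, 2, seed = 7)
  centers <- m$means[order(m$means[, 1]), ]
  expect_lt(max(abs(centers[1, ] - c(-5, -5))), 0.1)
  expect_lt(max(abs(centers[2, ] - c(5, 5))), 0.1)
  expect_lt(max(abs(m$weights - 0.5)), 0.05)
  expect_true(all(diff(m$loglik_trace) > -1e-8))
  expect_equal(sum(m$weights), 1, tolerance = 1e-12)
  # responsibilities row-normalize
  r <- gmm_responsibilities(m, X[1:50, ])
  expect_equal(rowSums(r), rep(1, 50), tolerance = 1e-12)
})

test_that("EM log-likelihood is monotone on assorted datasets", {
  set.seed(6)
  for (i in 1:3) {
    X <- matrix(rnorm(150 * 3, sd = i), 150, 3)
    m <- gmm_fit(X, 4, seed = i)
    expect_true(all(diff(m$loglik_trace) > -1e-8))
  }
  expect_error(gmm_fit(matrix(rnorm(6), 3, 2), 5), "K <= n")
})

test_that("the fitted mixture agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  X <- with_seed_test(32, rbind(
    matrix(rnorm(600, -3, 1), 300, 2),
    matrix(rnorm(600, 3, 1), 300, 2)))
  ours <- gmm_fit(X, 2, ridge = 0, seed = 5)
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  ours_centers <- ours$means[order(ours$means[, 1]), ]
  ref_centers <- t(ref$parameters$mean)[order(ref$parameters$mean[1, ]), ]
  expect_lt(max(abs(ours_centers - ref_centers)), 0.1)
  # achieved log-likelihood within a whisker of the reference optimum
  expect_gt(max(ours$loglik_trace), ref$loglik - 1)
})

test_that("GMR reduces to the linear-Gaussian conditional for K = 1", {
  set.seed(4)
  X <- cbind(rnorm(200), rnorm(200))
  X[, 2] <- 0.6 * X[, 1] + rnorm(200, 0, 0.3)
  m <- gmm_fit(X, 1, ridge = 1e-9, seed = 1)
  mu <- m$means[1, ]; S <- m$covs[[1]]
  for (q in c(-1.2, 0, 0.7)) {
    closed <- mu[2] + S[2, 1] / S[1, 1] * (q - mu[1])
    expect_equal(as.numeric(gmr_generalize(m, 1, 2, q)), closed,
                 tolerance = 1e-10)
  }
  expect_error(gmr_generalize(m, 1, 1, 0), "disjoint")
})

test_that("GMR recovers a noiseless line with K = 3 components", {
  x <- seq(-2, 2, length.out = 300)
  X <- cbind(x, 2 * x)
  m <- gmm_fit(X, 3, ridge = 1e-8, seed = 2)
  q <- seq(-1.8, 1.8, length.out = 25)
  pred <- gmr_generalize(m, 1, 2, matrix(q, ncol = 1))
  expect_lt(max(abs(pred - 2 * q)), 0.05)
})

test_that("responsibilities saturate at a well-separated component mean", {
  X <- with_seed_test(33, rbind(
    matrix(rnorm(400, -6, 0.3), 200, 2),
    matrix(rnorm(400, 6, 0.3), 200, 2)))
  m <- gmm_fit(X, 2, seed = 9)
  k <- which.min(m$means[, 1])
  pred <- gmr_generalize(m, 1, 2, m$means[k, 1])
  expect_lt(abs(pred - m$means[k, 2]), 1e-6)
})

test_that("segment encoding is a soft histogram plus GMR signal", {
  X <- with_seed_test(34, rbind(
    matrix(rnorm(300, -4, 0.4), 150, 2),
    matrix(rnorm(300, 4, 0.4), 150, 2)))
  m <- gmm_fit(X, 2, seed = 11)
  k2 <- which.max(m$means[, 1])
  at_mean <- matrix(m$means[k2, ], 1)
  codes <- encode_segments(m, list(at_mean))
  onehot <- rep(0, 2); onehot[k2] <- 1
  expect_equal(codes[[1]], onehot, tolerance = 1e-6)
  # empty descriptor set: zero histogram, unconditioned mean for the GMR part
  codes2 <- encode_segments(m, list(NULL), input_dims = 1, output_dims = 2,
                            query_list = list(matrix(NA_real_, 1, 1)))
  expect_equal(codes2[[1]][1:2], c(0, 0))
  expect_equal(codes2[[1]][3],
               sum(m$weights * m$means[, 2]), tolerance = 1e-12)
  # histogram additivity over concatenated descriptor sets
  A <- X[1:20, ]; B <- X[200:230, ]
  h <- function(D) encode_segments(m, list(D))[[1]]
  expect_equal(h(rbind(A, B)), h(A) + h(B), tolerance = 1e-9)
  # histogram block sums to the number of descriptors encoded
  expect_equal(sum(h(A)), nrow(A), tolerance = 1e-9)
  expect_error(encode_segments(m, list(matrix(0, 2, 5))), "dim")
})
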