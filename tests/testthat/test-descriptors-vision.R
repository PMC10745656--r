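test_that("thermal maps accumulate inter-frame change", {
  f <- matrix(10, 8, 8)
  tm0 <- thermal_map(list(f, f, f))
  expect_true(all(tm0$heat == 0))
  expect_equal(tm0$tm, 0)
  f2 <- f; f2[3, 4] <- 110
  tm1 <- thermal_map(list(f, f2))
  expect_equal(tm1$tm, log(101))
  expect_equal(sum(tm1$heat > 0), 1)
  expect_error(thermal_map(list(f)), "2 frames")
  # generator: walking frames churn more pixels than standing frames
  rec <- bench_rec()
  lab <- rec$truth$frame_labels
  walk <- which(lab == "walking")[5:20]
  stand <- which(lab == "standing")[5:20]
  tw <- thermal_map(rec$frames[walk])
  ts <- thermal_map(rec$frames[stand])
  expect_gt(tw$tm, ts$tm)
  # brute-force pixel-loop oracle for the summary on a small window
  small <- rec$frames[walk[1:3]]
  acc <- 0
  for (r in seq_len(nrow(small[[1]]))) {
    for (c in seq_len(ncol(small[[1]]))) {
      h <- abs(small[[2]][r, c] - small[[1]][r, c]) +
        abs(small[[3]][r, c] - small[[2]][r, c])
      acc <- acc + log1p(h)
    }
  }
  expect_equal(thermal_map(small)$tm, acc, tolerance = 1e-9)
})

test_that("thermal summary is permutation-invariant and monotone", {
  set.seed(3)
  h <- matrix(abs(rnorm(64, 0, 20)), 8, 8)
  f0 <- matrix(0, 8, 8)
  tm <- thermal_map(list(f0, h))$tm
  perm <- matrix(sample(h), 8, 8)
  expect_equal(thermal_map(list(f0, perm))$tm, tm, tolerance = 1e-9)
  h2 <- h; h2[1, 1] <- h2[1, 1] + 5
  expect_gt(thermal_map(list(f0, h2))$tm, tm)
})

test_that("GGD moment matching recovers known shapes", {
  for (theta in c(0.8, 1, 2, 3)) {
    x <- with_seed_test(100 + round(10 * theta), rgg(1e5, theta, sigma = 1.3))
    fit <- fit_ggd(x)
    expect_lt(abs(fit$theta - theta) / theta, 0.05)
  }
  # tighter windows stated for the Gaussian and Laplacian cases
  xg <- with_seed_test(21, rgg(1e5, 2))
  expect_true(fit_ggd(xg)$theta >= 1.9 && fit_ggd(xg)$theta <= 2.1)
  xl <- with_seed_test(22, rgg(1e5, 1))
  expect_true(fit_ggd(xl)$theta >= 0.93 && fit_ggd(xl)$theta <= 1.07)
  # scale equivariance
  f1 <- fit_ggd(xg); f2 <- fit_ggd(3.5 * xg)
  expect_equal(f2$sigma, 3.5 * f1$sigma, tolerance = 1e-9)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-9)
  expect_error(fit_ggd(rep(1, 100)), "degenerate")
  expect_error(fit_ggd(rnorm(10)), "50 samples")
})

test_that("saliency highlights rare structure and ignores DC shifts", {
  flat <- matrix(50, 32, 32)
  bank_rec <- bench_rec()
  bank <- fit_ggd_bank(bank_rec$frames[c(1, 60, 120)])
  s0 <- saliency_map(flat, bank)
  expect_true(all(s0 == 1e-9))
  # a bright patch on a textured background attracts the argmax
  set.seed(4)
  fr <- matrix(40 + rnorm(1024, 0, 2), 32, 32)
  fr[12:21, 12:21] <- 200
  bank2 <- fit_ggd_bank(list(fr))
  sal <- saliency_map(fr, bank2)
  peak <- which(sal == max(sal), arr.ind = TRUE)[1, ]
  expect_true(peak[1] >= 9 && peak[1] <= 24 && peak[2] >= 9 && peak[2] <= 24)
  # brute-force -log p check at one pixel
  ch <- mmhar:::bandpass_channels(fr)
  manual <- 0
  for (i in 1:3) {
    p <- bank2[[i]]
    v <- ch[[i]][15, 15]
    manual <- manual - (log(p$theta) - log(2 * p$sigma) - lgamma(1 / p$theta) -
                          abs(v / p$sigma)^p$theta)
  }
  raw <- Reduce(`+`, lapply(1:3, function(i) {
    -mmhar:::ggd_logpdf(ch[[i]], bank2[[i]])
  }))
  expect_equal(raw[15, 15], manual, tolerance = 1e-9)
  # DC invariance: band-pass channels kill constant offsets
  expect_equal(saliency_map(fr + 25, bank2), sal, tolerance = 1e-6)
})

test_that("orientation angles agree with the acos oracle and are similarity-invariant", {
  expect_equal(vec_angle(c(1, 0), c(0, 1)), pi / 2)
  expect_equal(vec_angle(c(1, 0), c(2, 0)), 0)
  expect_equal(vec_angle(c(1, 0), c(1, 1)),
               acos(sum(c(1, 0) * c(1, 1)) / sqrt(2)), tolerance = 1e-12)
  # full skeleton: rotation + translation + scaling leave angles unchanged
  pose <- mmhar:::canonical_pose()
  lm <- cbind(row = 10 + pose[, "y"] * 30, col = 20 + pose[, "x"] * 30)
  a1 <- orientation_angles(lm)$angles
  th <- 0.7; R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  lm2 <- t(R %*% t(lm)) * 2.3
  lm2 <- sweep(lm2, 2, c(5, -40), `+`)
  rownames(lm2) <- rownames(lm)
  a2 <- orientation_angles(lm2)$angles
  expect_equal(a2, a1, tolerance = 1e-9)
  expect_true(all(a1 >= 0 & a1 <= pi))
  # missing landmarks yield NA, not errors
  lm3 <- lm; lm3["wristL", ] <- NA
  a3 <- orientation_angles(lm3)
  expect_true(is.na(a3$angles[2]))
  expect_false(a3$valid[2])
})

test_that("SLIF web geometry follows the spoke-angle closed form", {
  img <- matrix(7.5, 30, 30)
  s <- slif(img, c(15, 15), N = 4, M = 1, ring_step = 5)
  expect_equal(s$nodes,
               rbind(c(20, 15), c(15, 20), c(10, 15), c(15, 10)),
               tolerance = 1e-9)
  expect_equal(s$samples, rep(7.5, 4))
  # n = 0 spoke lies on the positive first axis for every ring
  s2 <- slif(img, c(15, 15), N = 8, M = 3, ring_step = 2)
  for (m in 1:3) {
    expect_equal(s2$nodes[(m - 1) * 8 + 1, ], c(15 + 2 * m, 15),
                 tolerance = 1e-9)
  }
  # radial monotonicity: ring m+1 strictly farther than ring m
  d <- sqrt(rowSums(sweep(s2$nodes, 2, c(15, 15))^2))
  expect_true(all(d[9:16] > d[1:8]) && all(d[17:24] > d[9:16]))
  # constant image samples the constant regardless of geometry
  expect_equal(s2$samples, rep(7.5, 24))
  # out-of-frame nodes flagged and sampled as zero
  s3 <- slif(img, c(1, 1), N = 4, M = 1, ring_step = 5)
  expect_true(any(s3$outside))
  expect_true(all(s3$samples[s3$outside] == 0))
  expect_error(slif(img, c(5, 5), N = 2, M = 1), "3 spokes")
})
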