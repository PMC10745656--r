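test_that("Butterworth split passes DC and kills it in the high-pass branch", {
  cfg <- filter_config(sample_rate = 50)
  x <- rep(3.7, 400)
  sp <- butterworth_split(x, cfg)
  inner <- 50:350
  expect_lt(max(abs(sp$low[inner] - 3.7)), 1e-6)
  expect_lt(max(abs(sp$high[inner])), 1e-6)
})

test_that("a deep-passband sinusoid survives the low-pass with gain > 0.99", {
  cfg <- filter_config(sample_rate = 50, fc_low = 5)
  t <- (0:1999) / 50
  x <- sin(2 * pi * 0.05 * t)   # 0.01 * fc_low
  sp <- butterworth_split(x, cfg)
  inner <- 200:1800
  ratio <- max(abs(sp$low[inner])) / max(abs(x[inner]))
  expect_gt(ratio, 0.99)
})

test_that("low-pass magnitude response matches the analytic Butterworth gain", {
  # zero-phase filtering applies |H|^2; for order n and cutoff fc the
  # analytic gain at f is 1 / (1 + (f/fc)^(2n))
  cfg <- filter_config(order = 4, fc_low = 5, sample_rate = 50)
  t <- (0:3999) / 50
  for (f in c(0.5, 1, 2, 3)) {
    x <- sin(2 * pi * f * t)
    y <- butterworth_split(x, cfg)$low
    inner <- 500:3500
    gain_meas <- max(abs(y[inner]))
    gain_theo <- 1 / (1 + (f / 5)^8)
    expect_lt(abs(gain_meas - gain_theo), 0.01)
  }
  # stopband power of the low-pass output above 2*fc is < 1% of the passband
  x <- with_seed_test(42, stats::rnorm(4096))
  y <- butterworth_split(x, cfg)$low
  p <- periodogram(y, 256, hop = 128, sample_rate = 50)
  freqs <- (0:128) * 50 / 256
  pw <- colMeans(p)
  expect_lt(sum(pw[freqs > 10]), 0.01 * sum(pw[freqs <= 5]))
})

test_that("channel norm matches a brute-force Euclidean oracle", {
  expect_equal(channel_norm(matrix(0, 5, 3), matrix(0, 5, 3)), rep(0, 5))
  expect_equal(channel_norm(matrix(c(3, 4, 0), 1, 3), matrix(0, 1, 3)), 5)
  set.seed(3)
  lpf <- matrix(rnorm(300), 100, 3); hpf <- matrix(rnorm(300), 100, 3)
  oracle <- vapply(1:100, function(i) {
    s <- 0
    for (j in 1:3) s <- s + lpf[i, j]^2 + hpf[i, j]^2
    sqrt(s)
  }, numeric(1))
  expect_equal(channel_norm(lpf, hpf), oracle, tolerance = 1e-12)
  # the printed-sum reading is also available
  expect_equal(channel_norm(lpf, hpf, "as_printed_sum"),
               rowSums(lpf) + rowSums(hpf), tolerance = 1e-12)
  # Euclidean norm dominates any single component
  expect_true(all(channel_norm(lpf, hpf) >=
                    apply(abs(cbind(lpf, hpf)), 1, max) - 1e-12))
  expect_error(channel_norm(matrix(0, 4, 3), matrix(0, 5, 3)), "equal length")
})

test_that("gravity estimation returns min/mean magnitudes and the mean vector", {
  g <- estimate_gravity(matrix(c(0, 0, 9.81), 10, 3, byrow = TRUE))
  expect_equal(g$gm, 9.81); expect_equal(g$ga, 9.81)
  expect_equal(g$g_vec, c(0, 0, 9.81))
  g2 <- estimate_gravity(rbind(c(0, 0, 9.7), c(0, 0, 9.9)))
  expect_equal(g2$gm, 9.7); expect_equal(g2$ga, 9.8)
  acc <- with_seed_test(10, matrix(c(0, 0, 9.81), 1000, 3, byrow = TRUE) +
                          matrix(rnorm(3000, 0, 0.05), 1000, 3))
  expect_lt(abs(estimate_gravity(acc)$ga - 9.81), 0.01)
  expect_error(estimate_gravity(matrix(0, 0, 3)), "empty")
})

test_that("gravity removal cancels the scripted gravity signal", {
  rec <- cached("lying_exact", function() {
    generate_recording(script1("lying_down"), noise = zero_noise(), seed = 1)
  })
  acc <- as.matrix(rec$imu[, c("ax", "ay", "az")])
  g <- estimate_gravity(acc)
  out <- remove_gravity(acc, g, rec$truth$orientation)
  expect_lt(max(sqrt(rowSums(out^2))), 1e-6)
  # identity orientation: plain vector subtraction
  n <- nrow(acc)
  qi <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  out2 <- remove_gravity(acc, g, qi)
  expect_equal(out2, sweep(acc, 2, c(0, 0, g$ga), `-`), tolerance = 1e-12)
  # rotating body, noiseless, true orientation: residual << gravity.
  # The walking script adds body oscillation, so compare against that truth.
  w <- walking_rec()
  aw <- as.matrix(w$imu[, c("ax", "ay", "az")])
  lw <- remove_gravity(aw, estimate_gravity(acc), w$truth$orientation)
  osc <- vapply(seq_len(nrow(aw)), function(k) {
    as.numeric(sqrt(sum((aw[k, ] -
      mmhar:::q_world_to_sensor(w$truth$orientation[k, ], c(0, 0, 9.81)))^2)))
  }, numeric(1))
  expect_lt(max(abs(sqrt(rowSums(lw^2)) - osc)), 1e-3 * 9.81)
})

test_that("hard-iron offset is recovered exactly on static windows", {
  ref <- c(22, 5, -43)
  n <- 100
  off <- c(10, -3, 2)
  mag <- matrix(ref, n, 3, byrow = TRUE) + matrix(off, n, 3, byrow = TRUE)
  out <- remove_magnetic_error(mag, ref)
  expect_equal(out, matrix(ref, n, 3, byrow = TRUE), tolerance = 1e-9)
  expect_equal(remove_magnetic_error(matrix(ref, n, 3, byrow = TRUE), ref),
               matrix(ref, n, 3, byrow = TRUE), tolerance = 1e-12)
  expect_error(remove_magnetic_error(mag, c(0, 0, 0)), "non-zero")
  # rotating body with offset: correction reduces the magnitude scatter
  w <- generate_recording(script1("walking", 10),
                          noise = noise_config(sigma_acc = 0, sigma_gyro = 0,
                                               gyro_bias = c(0, 0, 0),
                                               sigma_mag = 0.2,
                                               mag_offset = c(8, -4, 3),
                                               frame_noise_sd = 0),
                          seed = 9)
  mw <- as.matrix(w$imu[, c("mx", "my", "mz")])
  cv <- function(m) {
    nn <- sqrt(rowSums(m^2)); stats::sd(nn) / mean(nn)
  }
  corrected <- remove_magnetic_error(mw, ref, w$truth$orientation)
  expect_lt(cv(corrected), cv(mw))
})

test_that("wavelet denoising leaves smooth signals alone and reduces noise MSE", {
  cfg <- filter_config()
  expect_equal(dwt_denoise(rep(0, 64), cfg), rep(0, 64))
  ramp <- seq(0, 1, length.out = 1024)
  expect_lt(max(abs(dwt_denoise(ramp, cfg) - ramp)), 1e-8)
  noisy <- ramp + with_seed_test(4, rnorm(1024, 0, 0.5))
  den <- dwt_denoise(noisy, cfg)
  expect_lt(mean((den - ramp)^2), mean((noisy - ramp)^2))
  expect_error(dwt_denoise(rep(0, 4), cfg), "too short")
})

test_that("the multilevel DWT reconstructs exactly, including odd lengths", {
  set.seed(6)
  for (n in c(64, 100, 37)) {
    x <- rnorm(n)
    lev <- if (n >= 64) 3 else 2
    expect_equal(dwt_inverse(dwt_forward(x, "db4", lev)), x, tolerance = 1e-10)
    expect_equal(dwt_inverse(dwt_forward(x, "haar", lev)), x, tolerance = 1e-10)
  }
})

test_that("orientation fusion holds the static fixed point and stays unit-norm", {
  cfg <- filter_config(sample_rate = 50, gd_step = 0.1)
  n <- 100
  os <- fuse_orientation(matrix(0, n, 3),
                         matrix(c(0, 0, 9.81), n, 3, byrow = TRUE), NULL, cfg)
  expect_lt(max(abs(sweep(os$q, 2, c(1, 0, 0, 0)))), 1e-6)
  expect_lt(max(abs(sqrt(rowSums(os$q^2)) - 1)), 1e-9)
})

test_that("constant-rate gyro integrates to the closed-form rotation angle", {
  cfg <- filter_config(sample_rate = 100, gd_step = 0)
  n <- 100
  gyro <- matrix(c(0, 0, pi / 2), n, 3, byrow = TRUE)
  accel <- matrix(c(0, 0, 9.81), n, 3, byrow = TRUE)
  os <- fuse_orientation(gyro, accel, NULL, cfg)
  qf <- os$q[n, ]
  angle_deg <- 2 * atan2(sqrt(sum(qf[2:4]^2)), qf[1]) * 180 / pi
  expect_lt(abs(angle_deg - 90), 0.5)
})

test_that("fusion tracks the generator's true orientation on scripted rotations", {
  w <- walking_rec()
  cfg <- filter_config(sample_rate = 50)
  pre <- preprocess_imu(w, cfg)
  err <- vapply(100:500, function(k) {
    mmhar:::q_angle_between(pre$orient$q[k, ], w$truth$orientation[k, ])
  }, numeric(1)) * 180 / pi
  expect_lt(mean(err), 5)
  expect_lt(max(abs(sqrt(rowSums(pre$orient$q^2)) - 1)), 1e-9)
})

test_that("euler angles follow the atan2 plane identities", {
  expect_equal(unname(euler_angles(c(1, 1, 1))), rep(pi / 4, 3))
  e <- euler_angles(c(1, 0, 1))
  expect_equal(unname(e[c("Axz", "Axy")]), c(pi / 4, 0))
  e2 <- euler_angles(c(0, 1, 1))
  expect_equal(unname(e2[c("Ayz", "Axy")]), c(pi / 4, pi / 2))
  expect_error(euler_angles(c(0, 0, 0)), "zero vector")
  # scale invariance and range
  set.seed(8)
  for (i in 1:20) {
    v <- rnorm(3)
    if (all(v == 0)) next
    expect_equal(euler_angles(v), euler_angles(2.7 * v), tolerance = 1e-12)
    expect_true(all(euler_angles(v) > -pi & euler_angles(v) <= pi))
  }
})

test_that("fusion rejects bad initial states and NaN inputs", {
  cfg <- filter_config(sample_rate = 50)
  a <- matrix(c(0, 0, 9.81), 10, 3, byrow = TRUE)
  expect_error(fuse_orientation(matrix(0, 10, 3), a, NULL, cfg,
                                q0 = c(2, 0, 0, 0)), "unit")
  g <- matrix(0, 10, 3); g[3, 1] <- NaN
  expect_error(fuse_orientation(g, a, NULL, cfg), "NaN")
  expect_error(butterworth_split(rep(1, 5), filter_config()), "shorter")
})
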