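test_that("a stationary noiseless body reads exactly gravity and the gyro bias", {
  bias <- c(0.02, -0.01, 0.005)
  nz <- noise_config(sigma_acc = 0, sigma_gyro = 0, gyro_bias = bias,
                     sigma_mag = 0, frame_noise_sd = 0)
  rec <- generate_recording(script1("lying_down"), noise = nz, seed = 2)
  mags <- sqrt(rowSums(as.matrix(rec$imu[, c("ax", "ay", "az")])^2))
  expect_equal(mags, rep(9.81, length(mags)), tolerance = 1e-12)
  gyro <- as.matrix(rec$imu[, c("gx", "gy", "gz")])
  expect_equal(unname(gyro), matrix(bias, nrow(gyro), 3, byrow = TRUE),
               tolerance = 1e-15)
})

test_that("same script and seed give a byte-identical recording", {
  sc <- activity_script(
    data.frame(start_s = c(0, 3), end_s = c(3, 6),
               label = c("standing", "walking")), 50, 8)
  r1 <- generate_recording(sc, noise = noise_config(), seed = 7)
  r2 <- generate_recording(sc, noise = noise_config(), seed = 7)
  expect_identical(r1, r2)
  r3 <- generate_recording(sc, noise = noise_config(), seed = 8)
  expect_false(identical(r1$imu, r3$imu))
})

test_that("per-interval accel variance matches the configured sinusoid closed form", {
  # var of a*sin(2 pi f t) over whole periods is a^2/2; 60 s per activity at
  # 50 Hz gives n = 6000 samples over an integer number of periods
  sc <- activity_script(
    data.frame(start_s = c(0, 60), end_s = c(60, 120),
               label = c("standing", "walking")), 50, 8)
  rec <- generate_recording(sc, noise = zero_noise(), seed = 1,
                            frame_size = c(24, 32))
  dyn <- activity_dynamics()
  for (act in c("standing", "walking")) {
    sel <- rec$truth$imu_labels == act
    a <- dyn$a_acc[dyn$activity == act]
    # x-axis oscillation has zero phase; remove the gravity component first
    g <- generate_recording(script1(act, 2, 50, 8), noise = zero_noise(),
                            seed = 1, frame_size = c(24, 32))
    v <- var(rec$imu$ax[sel] - mean(rec$imu$ax[sel]))
    expect_lt(abs(v - a^2 / 2) / (a^2 / 2), 0.05)
  }
})

test_that("every sample and frame carries exactly one label from the script", {
  rec <- bench_rec()
  expect_length(rec$truth$imu_labels, nrow(rec$imu))
  expect_length(rec$truth$frame_labels, length(rec$frames))
  vocab <- c(activity_vocabulary(), "none")
  expect_true(all(rec$truth$imu_labels %in% vocab))
  expect_true(all(rec$truth$frame_labels %in% vocab))
  # stream sizes follow duration x rate
  expect_equal(nrow(rec$imu), round(24 * 50))
  expect_equal(length(rec$frames), round(24 * 8))
})

test_that("ambient events reference layout sensors and alternate states", {
  rec <- bench_rec()
  ids <- rec$layout$sensors$sensor_id
  expect_true(all(rec$ambient$sensor_id %in% ids))
  for (id in unique(rec$ambient$sensor_id)) {
    st <- rec$ambient$state[rec$ambient$sensor_id == id]
    expect_true(all(abs(diff(st)) == 1))  # strict on/off alternation
  }
})

test_that("invalid scripts and noise configs are rejected", {
  expect_error(activity_script(data.frame()), "non-empty")
  expect_error(activity_script(
    data.frame(start_s = 0, end_s = 2, label = "flying")), "unknown activity")
  expect_error(activity_script(
    data.frame(start_s = c(0, 1), end_s = c(2, 3),
               label = c("walking", "standing"))), "overlap")
  expect_error(activity_script(
    data.frame(start_s = 0, end_s = 2, label = "walking"),
    sample_rate_imu = -5), "positive")
  expect_error(noise_config(sigma_acc = -1), ">= 0")
})

test_that("recordings round-trip through the plain-text writers", {
  rec <- generate_recording(script1("walking", 2), noise = noise_config(),
                            seed = 3, frame_size = c(24, 32))
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  imu <- read_imu_csv(file.path(dir, "imu.csv"))
  expect_equal(imu$ax, rec$imu$ax, tolerance = 1e-12)
  amb <- read_ambient_csv(file.path(dir, "ambient.csv"))
  expect_equal(nrow(amb), nrow(rec$ambient))
  lay <- read_layout_yaml(file.path(dir, "layout.yaml"))
  expect_equal(lay$sensors$sensor_id, rec$layout$sensors$sensor_id)
  expect_equal(lay$sensors$neighbors, rec$layout$sensors$neighbors)
})
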