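# Shared fixtures, built in code and cached per test run.

with_seed_test <- function(seed, code) mmhar:::with_seed(seed, code)

zero_noise <- function() {
  noise_config(sigma_acc = 0, sigma_gyro = 0, gyro_bias = c(0, 0, 0),
               sigma_mag = 0, mag_offset = c(0, 0, 0), frame_noise_sd = 0)
}

script1 <- function(label, dur = 4, fs = 50, fps = 8) {
  activity_script(data.frame(start_s = 0, end_s = dur, label = label),
                  sample_rate_imu = fs, fps_video = fps)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# noiseless walking recording (used by orientation / vision tests)
walking_rec <- function() cached("walking", function() {
  generate_recording(script1("walking", dur = 10), noise = zero_noise(),
                     seed = 5)
})

# noiseless multi-activity recording at benchmark structure
bench_rec <- function() cached("bench", function() {
  sc <- activity_script(
    data.frame(start_s = c(0, 6, 12, 18), end_s = c(6, 12, 18, 24),
               label = c("running", "standing", "lying_down", "walking")),
    sample_rate_imu = 50, fps_video = 8)
  generate_recording(sc, noise = zero_noise(), seed = 11)
})

# synthetic 12-blob mask at the canonical band positions of a 48 x 64 frame
canonical_blob_mask <- function(drop = character(0)) {
  pose <- mmhar:::canonical_pose()
  H <- 48; W <- 64
  h <- 0.8 * H; top <- 0.10 * H; cx <- W / 2
  mask <- matrix(0, H, W)
  centers <- list()
  for (nm in rownames(pose)) {
    if (nm %in% drop) next
    r <- round(top + pose[nm, "y"] * h)
    c <- round(cx + pose[nm, "x"] * h)
    mask[(r - 1):(r + 1), (c - 1):(c + 1)] <- 1
    centers[[nm]] <- c(r, c)
  }
  list(mask = mask, centers = centers)
}

# draw GGD samples by the gamma transform: |x| = sigma * G^(1/theta),
# G ~ Gamma(1/theta, 1), random sign
rgg <- function(n, theta, sigma = 1) {
  g <- stats::rgamma(n, shape = 1 / theta, rate = 1)
  sigma * g^(1 / theta) * sample(c(-1, 1), n, replace = TRUE)
}

# Separable two-class sequences: the class shifts the code mean by +/- 1
separable_data <- function(n_seq = 200, len = 5, d = 4, seed = 50) {
  with_seed_test(seed, {
    seqs <- vector("list", n_seq)
    labs <- vector("list", n_seq)
    for (i in seq_len(n_seq)) {
      cls <- if (i %% 2 == 0) "pos" else "neg"
      mu <- if (cls == "pos") 1 else -1
      seqs[[i]] <- matrix(rnorm(len * d, mu, 0.5), len, d)
      labs[[i]] <- rep(cls, len)
    }
    list(seqs = seqs, labs = labs)
  })
}
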