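#' Synthetic multimodal recordings
#'
#' Seeded generator for multimodal activity recordings with the structure the
#' decoding pipeline assumes: a scripted sequence of labelled activity
#' intervals drives (i) a 9-channel IMU stream (tri-axial accelerometer,
#' gyroscope, magnetometer), (ii) binary ambient sensor events fired when the
#' subject's position enters a sensor's zone, and (iii) low-resolution frames
#' showing an articulated stick figure on a static background. Ground-truth
#' orientation, position, per-sample labels and per-frame skeleton landmarks
#' are stored alongside, so every downstream stage can be validated against a
#' known answer.
#'
#' Activity dynamics follow a per-activity sinusoid bank: body acceleration is
#' a per-axis sinusoid of configured amplitude and frequency, the angular
#' velocity is a yaw-rate sinusoid plus a slow drift, and the orientation is
#' the exact analytic integral of that yaw rate composed with a per-activity
#' posture rotation. This makes closed-form expectations available for the
#' downstream descriptors (window variance, periodogram peaks, gravity
#' direction).
#'
#' @name synthetic_data
NULL

#' Activity vocabulary and dynamics table
#'
#' @return data.frame with one row per supported activity: oscillation
#'   frequency/amplitude for body acceleration (`f_acc` Hz, `a_acc` m/s^2) and
#'   yaw rate (`f_gyro` Hz, `a_gyro` rad/s), a slow yaw drift (rad/s),
#'   translation speed across the room (room-widths/s), limb swing amplitude
#'   (dimensionless, scales the stick-figure limb excursion) and posture.
#' @export
activity_dynamics <- function() {
  data.frame(
    activity = c("lying_down", "sitting", "standing", "walking", "running"),
    f_acc    = c(0,    0.4,  0.8,  1.8,  2.8),
    a_acc    = c(0,    0.10, 0.30, 2.00, 4.50),
    f_gyro   = c(0,    0.4,  0.8,  1.8,  2.8),
    a_gyro   = c(0,    0.02, 0.05, 0.60, 1.20),
    drift    = c(0,    0,    0,    0.02, 0.03),
    speed    = c(0,    0,    0,    0.08, 0.16),
    swing    = c(0,    0.05, 0.10, 0.55, 0.90),
    posture  = c("lying", "upright", "upright", "upright", "upright"),
    stringsAsFactors = FALSE
  )
}

#' @rdname synthetic_data
#' @export
activity_vocabulary <- function() activity_dynamics()$activity

#' Build an activity script
#'
#' @param intervals data.frame with columns `start_s`, `end_s`, `label`;
#'   intervals must be sorted, non-overlapping, with `end_s > start_s` and
#'   labels from [activity_vocabulary()].
#' @param sample_rate_imu IMU sampling rate in Hz.
#' @param fps_video frame rate of the rendered video.
#' @return an `activity_script` object.
#' @export
activity_script <- function(intervals, sample_rate_imu = 50, fps_video = 8) {
  assert_that(is.data.frame(intervals) && nrow(intervals) > 0,
              "intervals must be a non-empty data.frame")
  assert_that(all(c("start_s", "end_s", "label") %in% names(intervals)),
              "intervals needs columns start_s, end_s, label")
  assert_that(sample_rate_imu > 0 && fps_video > 0, "rates must be positive")
  intervals <- intervals[order(intervals$start_s), , drop = FALSE]
  assert_that(all(intervals$end_s > intervals$start_s),
              "every interval needs end_s > start_s")
  if (nrow(intervals) > 1) {
    assert_that(all(intervals$start_s[-1] >= intervals$end_s[-nrow(intervals)] - 1e-12),
                "intervals must not overlap")
  }
  bad <- setdiff(intervals$label, activity_vocabulary())
  assert_that(length(bad) == 0, "unknown activity label(s): %s",
              paste(bad, collapse = ", "))
  structure(list(intervals = intervals,
                 sample_rate_imu = sample_rate_imu,
                 fps_video = fps_video,
                 duration_s = max(intervals$end_s)),
            class = "activity_script")
}

#' Sensor noise configuration
#'
#' Standard deviations of additive white Gaussian noise per modality, a
#' constant gyroscope bias and a magnetometer hard-iron offset. The paper's
#' datasets publish no sensor noise model; these defaults are generator
#' fixtures chosen at consumer-IMU magnitudes, not claims about any dataset.
#'
#' @param sigma_acc accel noise sd (m/s^2). @param sigma_gyro gyro noise sd
#'   (rad/s). @param gyro_bias length-3 constant gyro bias (rad/s).
#' @param sigma_mag magnetometer noise sd (uT). @param mag_offset length-3
#'   hard-iron offset (uT). @param frame_noise_sd pixel noise sd (intensity).
#' @export
noise_config <- function(sigma_acc = 0.05, sigma_gyro = 0.01,
                         gyro_bias = c(0.01, -0.005, 0.002),
                         sigma_mag = 0.3, mag_offset = c(0, 0, 0),
                         frame_noise_sd = 2) {
  assert_that(sigma_acc >= 0 && sigma_gyro >= 0 && sigma_mag >= 0 &&
                frame_noise_sd >= 0, "noise standard deviations must be >= 0")
  structure(list(sigma_acc = sigma_acc, sigma_gyro = sigma_gyro,
                 gyro_bias = vec3(gyro_bias), sigma_mag = sigma_mag,
                 mag_offset = vec3(mag_offset), frame_noise_sd = frame_noise_sd),
            class = "noise_config")
}

#' Ambient sensor layout
#'
#' A set of environment-mounted binary sensors, each with a type, a mounting
#' orientation (degrees), a symmetric neighbour relation and a zone
#' (an interval of the normalized room coordinate in which the sensor is
#' active).
#'
#' @param sensors data.frame with columns `sensor_id`, `sensor_type`
#'   (switch/PIR/infrared), `orientation` (degrees in [0, 360)), `zone_lo`,
#'   `zone_hi` (normalized room x), and `neighbors` (list-column of ids).
#' @export
ambient_layout <- function(sensors) {
  assert_that(is.data.frame(sensors) && nrow(sensors) > 0,
              "sensors must be a non-empty data.frame")
  assert_that(!anyDuplicated(sensors$sensor_id), "sensor ids must be unique")
  assert_that(all(sensors$sensor_type %in% c("switch", "PIR", "infrared")),
              "sensor_type must be switch, PIR or infrared")
  assert_that(all(sensors$orientation >= 0 & sensors$orientation < 360),
              "orientation must lie in [0, 360)")
  ids <- sensors$sensor_id
  for (i in seq_len(nrow(sensors))) {
    for (nb in sensors$neighbors[[i]]) {
      assert_that(nb %in% ids, "neighbor '%s' of '%s' is not a sensor id",
                  nb, ids[i])
      j <- match(nb, ids)
      assert_that(ids[i] %in% sensors$neighbors[[j]],
                  "neighbor relation asymmetric for pair (%s, %s)", ids[i], nb)
    }
  }
  structure(list(sensors = sensors), class = "ambient_layout")
}

#' @rdname ambient_layout
#' @export
default_ambient_layout <- function() {
  sensors <- data.frame(
    sensor_id = c("door_switch", "pir_hall", "pir_room", "chair_switch"),
    sensor_type = c("switch", "PIR", "PIR", "switch"),
    orientation = c(0, 90, 180, 270),
    zone_lo = c(0.00, 0.20, 0.50, 0.75),
    zone_hi = c(0.25, 0.55, 0.80, 1.00),
    stringsAsFactors = FALSE
  )
  sensors$neighbors <- list(c("pir_hall"), c("door_switch", "pir_room"),
                            c("pir_hall", "chair_switch"), c("pir_room"))
  ambient_layout(sensors)
}

# ---- internal kinematics -----------------------------------------------

GRAVITY <- 9.81
MAG_REFERENCE <- c(22, 5, -43)  # uT, fixed reference field

posture_quaternion <- function(posture) {
  switch(posture,
         upright = q_identity(),
         lying   = q_from_axis_angle(c(1, 0, 0), pi / 2),
         stopf("unknown posture '%s'", posture))
}

# Analytic yaw angle and yaw rate at times t for one interval's dynamics,
# starting from yaw psi0 at t0. psi_dot = drift + a*sin(2 pi f (t - t0)).
interval_yaw <- function(t, t0, psi0, f, a, drift) {
  dt <- t - t0
  rate <- drift + a * sin(2 * pi * f * dt)
  psi <- if (f > 0) {
    psi0 + drift * dt + a * (1 - cos(2 * pi * f * dt)) / (2 * pi * f)
  } else {
    psi0 + drift * dt
  }
  list(psi = psi, rate = rate)
}

# Per-sample activity row index (0 = none) for times t
interval_index_at <- function(script, t) {
  idx <- integer(length(t))
  iv <- script$intervals
  for (i in seq_len(nrow(iv))) {
    inside <- t >= iv$start_s[i] & t < iv$end_s[i]
    idx[inside] <- i
  }
  # closing endpoint belongs to the final interval
  idx[t == iv$end_s[nrow(iv)]] <- nrow(iv)
  idx
}

# ---- stick figure ------------------------------------------------------

SKELETON_CATEGORIES <- c("head", "shoulders", "elbows", "wrists", "torso",
                         "knees", "ankles")

skeleton_landmarks <- function() {
  c("head", "shoulderL", "shoulderR", "elbowL", "elbowR", "wristL", "wristR",
    "torso", "kneeL", "kneeR", "ankleL", "ankleR")
}

# Canonical pose in body coordinates: y is the fraction of figure height from
# the head top (downwards), x a signed fraction of figure height. The y values
# are chosen so that, measured inside the landmark bounding box, each category
# falls inside its assignment band (see extract_skeleton).
canonical_pose <- function() {
  m <- rbind(
    head      = c(0.05,  0.00),
    shoulderL = c(0.18, -0.10), shoulderR = c(0.18, 0.10),
    elbowL    = c(0.32, -0.13), elbowR    = c(0.32, 0.13),
    wristL    = c(0.46, -0.15), wristR    = c(0.46, 0.15),
    torso     = c(0.40,  0.00),
    kneeL     = c(0.66, -0.10), kneeR     = c(0.66, 0.10),
    ankleL    = c(0.90, -0.13), ankleR    = c(0.90, 0.13)
  )
  colnames(m) <- c("y", "x")
  m
}

skeleton_bones <- function() {
  list(c("head", "torso"),
       c("shoulderL", "shoulderR"),
       c("shoulderL", "elbowL"), c("elbowL", "wristL"),
       c("shoulderR", "elbowR"), c("elbowR", "wristR"),
       c("torso", "kneeL"), c("kneeL", "ankleL"),
       c("torso", "kneeR"), c("kneeR", "ankleR"))
}

# Pose at phase ph (radians) with limb swing amplitude `swing`; x offsets of
# distal limb landmarks oscillate in antiphase left/right. y coordinates stay
# fixed so the band structure of the figure is preserved.
posed_landmarks <- function(ph, swing) {
  pose <- canonical_pose()
  s <- 0.06 * swing * sin(ph)
  pose["elbowL", "x"] <- pose["elbowL", "x"] + s
  pose["wristL", "x"] <- pose["wristL", "x"] + 1.8 * s
  pose["elbowR", "x"] <- pose["elbowR", "x"] - s
  pose["wristR", "x"] <- pose["wristR", "x"] - 1.8 * s
  pose["kneeL", "x"]  <- pose["kneeL", "x"] - 0.8 * s
  pose["ankleL", "x"] <- pose["ankleL", "x"] - 1.5 * s
  pose["kneeR", "x"]  <- pose["kneeR", "x"] + 0.8 * s
  pose["ankleR", "x"] <- pose["ankleR", "x"] + 1.5 * s
  pose
}

line_mask <- function(mask, r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0), 1) + 1
  rr <- round(seq(r0, r1, length.out = n))
  cc <- round(seq(c0, c1, length.out = n))
  keep <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
  mask[cbind(rr[keep], cc[keep])] <- TRUE
  mask
}

draw_blob <- function(img, r, c, value, half = 1) {
  rr <- max(1, round(r) - half):min(nrow(img), round(r) + half)
  cc <- max(1, round(c) - half):min(ncol(img), round(c) + half)
  img[rr, cc] <- value
  img
}

# Render one frame: static background, dim limb lines (below the default
# subtraction threshold) and bright landmark blobs that blob analysis can
# separate. Returns list(frame, landmarks) with landmarks as (row, col).
render_frame <- function(bg, pos_x, ph, swing, posture, fig_height_frac = 0.8) {
  H <- nrow(bg); W <- ncol(bg)
  pose <- posed_landmarks(ph, swing)
  h <- fig_height_frac * H
  margin <- 0.18 * W
  cx <- margin + pos_x * (W - 2 * margin)
  if (posture == "lying") {
    # body axis horizontal along the floor
    rows <- 0.72 * H + pose[, "x"] * h * 0.8
    cols <- cx + (pose[, "y"] - 0.475) * h * 0.9
  } else {
    top <- 0.10 * H
    rows <- top + pose[, "y"] * h
    cols <- cx + pose[, "x"] * h
  }
  lm <- cbind(row = rows, col = cols)
  img <- bg
  # limbs: a dim +35 offset over the local background (kept below the default
  # subtraction threshold so blob analysis sees the landmarks, not the bones)
  lmask <- matrix(FALSE, H, W)
  for (b in skeleton_bones()) {
    lmask <- line_mask(lmask, lm[b[1], 1], lm[b[1], 2], lm[b[2], 1], lm[b[2], 2])
  }
  img[lmask] <- pmin(img[lmask] + 35, 255)
  for (k in seq_len(nrow(lm))) img <- draw_blob(img, lm[k, 1], lm[k, 2], 255)
  list(frame = img, landmarks = lm)
}

# ---- main generator ----------------------------------------------------

#' Generate a synthetic multimodal recording
#'
#' @param script an [activity_script()].
#' @param layout an [ambient_layout()]; default [default_ambient_layout()].
#' @param noise a [noise_config()].
#' @param seed integer; together with the arguments it fully determines the
#'   output (same inputs give a bit-identical recording).
#' @param frame_size c(height, width) in pixels of the rendered frames.
#' @param mag_reference world-frame magnetic reference field (uT).
#' @return an `mm_recording`: IMU data.frame (`time_s`, `ax..az`, `gx..gz`,
#'   `mx..mz`), ambient event data.frame (`time_s`, `sensor_id`, `state`),
#'   list of H x W frames (0-255), and a `truth` list holding per-sample
#'   labels, the exact orientation quaternions, subject position, per-frame
#'   labels and skeleton landmark coordinates.
#' @export
generate_recording <- function(script, layout = default_ambient_layout(),
                               noise = noise_config(), seed = 1,
                               frame_size = c(48, 64),
                               mag_reference = MAG_REFERENCE) {
  assert_that(inherits(script, "activity_script"), "script must be an activity_script")
  assert_that(inherits(layout, "ambient_layout"), "layout must be an ambient_layout")
  assert_that(inherits(noise, "noise_config"), "noise must be a noise_config")
  dyn <- activity_dynamics()
  dur <- script$duration_s
  fs <- script$sample_rate_imu
  n <- round(dur * fs)
  t <- (seq_len(n) - 1) / fs
  idx <- interval_index_at(script, t)
  labels <- ifelse(idx > 0, script$intervals$label[pmax(idx, 1)], "none")

  # --- exact kinematics: yaw, orientation, position, per-sample truth
  psi <- numeric(n); rate <- numeric(n); pos <- numeric(n)
  acc_true <- matrix(0, n, 3)
  psi0 <- 0; pos0 <- 0.1; dir <- 1
  iv <- script$intervals
  phases <- c(0, 2 * pi / 3, 4 * pi / 3)
  quat <- matrix(0, n, 4)
  for (i in seq_len(nrow(iv))) {
    d <- dyn[match(iv$label[i], dyn$activity), ]
    sel <- which(idx == i)
    if (!length(sel)) next
    yw <- interval_yaw(t[sel], iv$start_s[i], psi0, d$f_gyro, d$a_gyro, d$drift)
    psi[sel] <- yw$psi; rate[sel] <- yw$rate
    # position: moving activities translate at constant speed with
    # reflection off the room ends; static activities settle at a
    # per-interval station (the subject moves between activity spots),
    # which also keeps any one pixel's figure coverage sparse enough for
    # median background recovery
    if (d$speed > 0) {
      for (k in sel) {
        dt <- 1 / fs
        step <- d$speed * dt * dir
        p <- pos0 + step
        if (p > 0.95) { p <- 0.95 - (p - 0.95); dir <- -dir }
        if (p < 0.05) { p <- 0.05 + (0.05 - p); dir <- -dir }
        pos[k] <- p; pos0 <- p
      }
    } else {
      stations <- c(0.2, 0.8, 0.4, 0.62, 0.1, 0.9)
      p <- stations[(i - 1) %% length(stations) + 1]
      pos[sel] <- p; pos0 <- p
    }
    osc_t <- t[sel] - iv$start_s[i]
    for (ax in 1:3) {
      acc_true[sel, ax] <- d$a_acc * sin(2 * pi * d$f_acc * osc_t + phases[ax])
    }
    pq <- posture_quaternion(d$posture)
    for (k in sel) {
      quat[k, ] <- q_mul(pq, q_from_axis_angle(c(0, 0, 1), psi[k]))
    }
    psi0 <- psi[sel[length(sel)]]
  }
  # samples outside any interval: hold the previous state
  if (any(idx == 0)) {
    for (k in which(idx == 0)) {
      j <- if (k > 1) k - 1 else which(idx > 0)[1]
      quat[k, ] <- quat[j, ]; pos[k] <- pos[j]
    }
  }

  grav_world <- c(0, 0, GRAVITY)
  accel <- gyro <- mag <- matrix(0, n, 3)
  for (k in seq_len(n)) {
    accel[k, ] <- q_world_to_sensor(quat[k, ], grav_world) + acc_true[k, ]
    gyro[k, ] <- c(0, 0, rate[k])
    mag[k, ] <- q_world_to_sensor(quat[k, ], mag_reference)
  }
  with_seed(derive_seed(seed, "imu"), {
    accel <- accel + matrix(stats::rnorm(3 * n, 0, noise$sigma_acc), n, 3)
    gyro <- gyro + matrix(noise$gyro_bias, n, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n, 0, noise$sigma_gyro), n, 3)
    mag <- mag + matrix(noise$mag_offset, n, 3, byrow = TRUE) +
      matrix(stats::rnorm(3 * n, 0, noise$sigma_mag), n, 3)
  })
  imu <- data.frame(time_s = t,
                    ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                    gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3],
                    mx = mag[, 1], my = mag[, 2], mz = mag[, 3])

  # --- ambient events from zone crossings of the subject position
  sensors <- layout$sensors
  events <- list()
  for (s in seq_len(nrow(sensors))) {
    inside <- pos >= sensors$zone_lo[s] & pos <= sensors$zone_hi[s]
    ch <- which(diff(inside) != 0)
    st <- inside[c(1, ch + 1)]
    tt <- t[c(1, ch + 1)]
    events[[s]] <- data.frame(time_s = tt, sensor_id = sensors$sensor_id[s],
                              state = as.integer(st))
  }
  ambient <- do.call(rbind, events)
  ambient <- ambient[order(ambient$time_s, ambient$sensor_id), , drop = FALSE]
  rownames(ambient) <- NULL

  # --- frames
  fps <- script$fps_video
  nf <- round(dur * fps)
  ft <- (seq_len(nf) - 1) / fps
  fidx <- interval_index_at(script, ft)
  flabels <- ifelse(fidx > 0, iv$label[pmax(fidx, 1)], "none")
  H <- frame_size[1]; W <- frame_size[2]
  bg <- with_seed(derive_seed(seed, "background"), {
    base <- matrix(40, H, W) + outer(seq_len(H), seq_len(W),
                                     function(r, c) 10 * c / W + 5 * r / H)
    round(pmin(pmax(base + matrix(stats::rnorm(H * W, 0, 3), H, W), 20), 80))
  })
  frames <- vector("list", nf)
  skeleton_truth <- vector("list", nf)
  imu_at <- pmin(n, pmax(1, round(ft * fs) + 1))
  frame_noise <- with_seed(derive_seed(seed, "frames"),
                           stats::rnorm(nf * H * W, 0, noise$frame_noise_sd))
  for (j in seq_len(nf)) {
    i <- fidx[j]
    d <- if (i > 0) dyn[match(iv$label[i], dyn$activity), ] else
      dyn[dyn$activity == "standing", ]
    ph <- if (i > 0) 2 * pi * d$f_gyro * (ft[j] - iv$start_s[i]) else 0
    rf <- render_frame(bg, pos[imu_at[j]], ph, d$swing, d$posture)
    fr <- rf$frame + matrix(frame_noise[((j - 1) * H * W + 1):(j * H * W)], H, W)
    frames[[j]] <- pmin(pmax(fr, 0), 255)
    skeleton_truth[[j]] <- rf$landmarks
  }

  structure(list(
    imu = imu, ambient = ambient, frames = frames, frame_times = ft,
    layout = layout, script = script, noise = noise, seed = seed,
    background = bg,
    truth = list(imu_labels = labels, frame_labels = flabels,
                 orientation = quat, position = pos,
                 skeleton = skeleton_truth)
  ), class = "mm_recording")
}

#' @export
print.mm_recording <- function(x, ...) {
  cat(sprintf("<mm_recording> %.1f s, %d IMU samples @ %g Hz, %d frames @ %g fps, %d ambient events\n",
              x$script$duration_s, nrow(x$imu), x$script$sample_rate_imu,
              length(x$frames), x$script$fps_video, nrow(x$ambient)))
  invisible(x)
}

#' Write a recording to plain-text files
#'
#' Writes `imu.csv`, `ambient.csv`, `truth.csv` (per-sample labels),
#' `layout.yaml`, and optionally per-frame PNGs under `frames/`.
#'
#' @param rec an `mm_recording`. @param dir output directory.
#' @param frames_png also write frames as PNG (requires the png package).
#' @export
write_recording <- function(rec, dir, frames_png = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rec$imu, file.path(dir, "imu.csv"), row.names = FALSE)
  utils::write.csv(rec$ambient, file.path(dir, "ambient.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time_s = rec$imu$time_s,
                              label = rec$truth$imu_labels),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  write_layout_yaml(rec$layout, file.path(dir, "layout.yaml"))
  if (frames_png) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stopf("frames_png = TRUE requires the png package")
    }
    fd <- file.path(dir, "frames")
    dir.create(fd, showWarnings = FALSE)
    for (j in seq_along(rec$frames)) {
      png::writePNG(rec$frames[[j]] / 255,
                    file.path(fd, sprintf("frame_%05d.png", j)))
    }
  }
  invisible(dir)
}
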