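#' IMU filtration configuration
#'
#' Parameters of the quaternion-based filtration chain. The source datasets
#' publish no filter settings, so these are package defaults: a 4th-order
#' Butterworth pair (5 Hz low-pass for the motion band, 0.3 Hz high-pass to
#' strip drift), a 3-level db4 wavelet denoiser for the gyroscope, and a
#' gradient-descent correction step of 0.1 for the orientation filter.
#'
#' @param order Butterworth order (>= 1).
#' @param fc_low low-pass cutoff, Hz. @param fc_high high-pass cutoff, Hz.
#' @param sample_rate sampling rate, Hz (cutoffs must be below Nyquist).
#' @param wavelet_name "db4" or "haar". @param dwt_level DWT depth (>= 1).
#' @param gd_step gradient-descent step of the orientation correction
#'   (0 disables the correction, leaving pure gyro integration).
#' @param norm_mode "euclidean" (the default reading of the combined-channel
#'   norm) or "as_printed_sum" (plain sum of the six filtered components).
#' @export
filter_config <- function(order = 4, fc_low = 5, fc_high = 0.3,
                          sample_rate = 50, wavelet_name = "db4",
                          dwt_level = 3, gd_step = 0.1,
                          norm_mode = c("euclidean", "as_printed_sum")) {
  norm_mode <- match.arg(norm_mode)
  assert_that(order >= 1, "order must be >= 1")
  assert_that(fc_low > 0 && fc_low < sample_rate / 2,
              "fc_low must lie in (0, sample_rate/2)")
  assert_that(fc_high > 0 && fc_high < sample_rate / 2,
              "fc_high must lie in (0, sample_rate/2)")
  assert_that(dwt_level >= 1, "dwt_level must be >= 1")
  assert_that(gd_step >= 0, "gd_step must be >= 0")
  structure(list(order = order, fc_low = fc_low, fc_high = fc_high,
                 sample_rate = sample_rate, wavelet_name = wavelet_name,
                 dwt_level = dwt_level, gd_step = gd_step,
                 norm_mode = norm_mode),
            class = "filter_config")
}

# Zero-phase filtering with odd-reflection padding at both ends; the pad must
# cover the filter's transient, which scales with the cutoff period.
filtfilt_reflect <- function(filt, x, pad = 24) {
  n <- length(x)
  p <- min(n - 1, max(pad, 9 * length(filt$b)))
  left <- 2 * x[1] - rev(x[2:(p + 1)])
  right <- 2 * x[n] - rev(x[(n - p):(n - 1)])
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(p + 1):(p + n)]
}

#' Split a series into low- and high-pass Butterworth components
#'
#' Zero-phase (forward-backward) filtering so descriptors are not
#' phase-shifted relative to the activity labels. A least-squares linear
#' trend is removed before filtering and restored on the low-pass branch,
#' which makes constant inputs exact fixed points (low = input, high = 0).
#'
#' @param x uniformly sampled numeric series.
#' @param cfg a [filter_config()].
#' @return list with `low` and `high` series, same length as `x`.
#' @export
butterworth_split <- function(x, cfg = filter_config()) {
  assert_that(all(is.finite(x)), "input contains non-finite values")
  assert_that(length(x) > 3 * cfg$order,
              "series of length %d is shorter than the filter warm-up (need > %d)",
              length(x), 3 * cfg$order)
  n <- length(x)
  tt <- seq_len(n) - (n + 1) / 2
  slope <- sum(tt * (x - mean(x))) / sum(tt^2)
  trend <- mean(x) + slope * tt
  r <- x - trend
  ny <- cfg$sample_rate / 2
  lp <- signal::butter(cfg$order, cfg$fc_low / ny, type = "low")
  hp <- signal::butter(cfg$order, cfg$fc_high / ny, type = "high")
  list(low = filtfilt_reflect(lp, r,
                              pad = ceiling(3 * cfg$sample_rate / cfg$fc_low)) +
         trend,
       high = filtfilt_reflect(hp, r,
                               pad = ceiling(3 * cfg$sample_rate / cfg$fc_high)))
}

#' Combined magnitude of the six filtered components
#'
#' Combines the three low-pass and three high-pass filtered axis signals into
#' one per-sample magnitude. The default is the Euclidean reading
#' sqrt(sum(LPF_i^2) + sum(HPF_i^2)); `mode = "as_printed_sum"` instead takes
#' the plain sum of the six components.
#'
#' @param lpf n x 3 matrix of low-pass filtered axes.
#' @param hpf n x 3 matrix of high-pass filtered axes.
#' @param mode "euclidean" or "as_printed_sum".
#' @return numeric series of length n.
#' @export
channel_norm <- function(lpf, hpf, mode = c("euclidean", "as_printed_sum")) {
  mode <- match.arg(mode)
  lpf <- as.matrix(lpf); hpf <- as.matrix(hpf)
  assert_that(nrow(lpf) == nrow(hpf) && ncol(lpf) == 3 && ncol(hpf) == 3,
              "lpf and hpf must be n x 3 matrices of equal length")
  if (mode == "euclidean") {
    sqrt(rowSums(lpf^2) + rowSums(hpf^2))
  } else {
    rowSums(lpf) + rowSums(hpf)
  }
}

#' Estimate gravity from a stationary interval
#'
#' @param accel n x 3 accelerometer samples (m/s^2) over a stationary span.
#' @return a `gravity_model`: `gm` (minimum per-sample magnitude), `ga`
#'   (average magnitude) and `g_vec` (mean acceleration vector, the gravity
#'   direction in the stationary sensor frame).
#' @export
estimate_gravity <- function(accel) {
  accel <- as.matrix(accel)
  assert_that(nrow(accel) >= 1, "stationary interval is empty")
  norms <- row_norms(accel)
  structure(list(gm = min(norms), ga = mean(norms), g_vec = colMeans(accel)),
            class = "gravity_model")
}

#' Remove the gravitational component from accelerometer samples
#'
#' Subtracts the world-frame gravity vector rotated into the sensor frame by
#' the per-sample orientation.
#'
#' @param accel n x 3 accelerometer series.
#' @param g a `gravity_model` from [estimate_gravity()]; its magnitude `ga`
#'   sets the world gravity (0, 0, ga).
#' @param orient an `orientation_state` (see [fuse_orientation()]) aligned
#'   with `accel`, or an n x 4 quaternion matrix.
#' @return n x 3 linear-acceleration series.
#' @export
remove_gravity <- function(accel, g, orient) {
  accel <- as.matrix(accel)
  q <- if (inherits(orient, "orientation_state")) orient$q else as.matrix(orient)
  assert_that(!is.null(q) && nrow(q) == nrow(accel),
              "orientation missing or not aligned with accel (%d vs %d rows)",
              if (is.null(q)) 0L else nrow(q), nrow(accel))
  g_world <- c(0, 0, g$ga)
  out <- accel
  for (k in seq_len(nrow(accel))) {
    out[k, ] <- accel[k, ] - q_world_to_sensor(q[k, ], g_world)
  }
  out
}

#' Remove hard-iron magnetic error
#'
#' Estimates a constant per-axis offset as the difference between the mean
#' measured field and the mean reference field (rotated per-sample into the
#' sensor frame when an orientation is supplied) and subtracts it.
#'
#' @param mag n x 3 magnetometer series (uT).
#' @param reference_field world-frame reference field, non-zero 3-vector.
#' @param orient optional `orientation_state` or n x 4 quaternion matrix.
#' @return corrected n x 3 magnetometer series.
#' @export
remove_magnetic_error <- function(mag, reference_field = MAG_REFERENCE,
                                  orient = NULL) {
  mag <- as.matrix(mag)
  reference_field <- vec3(reference_field)
  assert_that(sqrt(sum(reference_field^2)) > 0, "reference field must be non-zero")
  if (is.null(orient)) {
    ref_mean <- reference_field
  } else {
    q <- if (inherits(orient, "orientation_state")) orient$q else as.matrix(orient)
    assert_that(nrow(q) == nrow(mag), "orientation not aligned with mag")
    ref_rot <- t(vapply(seq_len(nrow(mag)),
                        function(k) q_world_to_sensor(q[k, ], reference_field),
                        numeric(3)))
    ref_mean <- colMeans(ref_rot)
  }
  offset <- colMeans(mag) - ref_mean
  sweep(mag, 2, offset, `-`)
}

# One Madgwick-style gradient step: returns the normalized objective gradient
# for the gravity (and optionally field) direction misalignment. The magnetic
# objective uses the full 3-D reference direction (not the horizontal-plane
# reduction), so yaw is corrected in the reference frame of the configured
# field rather than relative to magnetic north; its gradient is evaluated by
# central differences.
madgwick_gradient <- function(q, a_hat, m_hat = NULL, ref_unit = NULL) {
  q1 <- q[1]; q2 <- q[2]; q3 <- q[3]; q4 <- q[4]
  f <- c(2 * (q2 * q4 - q1 * q3) - a_hat[1],
         2 * (q1 * q2 + q3 * q4) - a_hat[2],
         1 - 2 * (q2^2 + q3^2) - a_hat[3])
  J <- matrix(c(-2 * q3, 2 * q4, -2 * q1, 2 * q2,
                2 * q2, 2 * q1, 2 * q4, 2 * q3,
                0, -4 * q2, -4 * q3, 0), nrow = 3, byrow = TRUE)
  grad <- as.numeric(crossprod(J, f))
  if (!is.null(m_hat) && !is.null(ref_unit)) {
    obj <- function(qq) {
      d <- q_world_to_sensor(qq / sqrt(sum(qq^2)), ref_unit) - m_hat
      0.5 * sum(d^2)
    }
    eps <- 1e-6
    gm <- vapply(1:4, function(i) {
      qp <- q; qp[i] <- qp[i] + eps
      qm <- q; qm[i] <- qm[i] - eps
      (obj(qp) - obj(qm)) / (2 * eps)
    }, numeric(1))
    grad <- grad + gm
  }
  n <- sqrt(sum(grad^2))
  if (n > 0) grad / n else grad
}

#' Fuse gyro, accel and magnetometer into an orientation trajectory
#'
#' Integrates the quaternion derivative q_dot = 1/2 q x (0, gyro) and applies
#' a normalized gradient-descent correction of size `gd_step` that reduces the
#' misalignment between the orientation-predicted and measured gravity
#' direction (and magnetic field direction when `mag` is given). The
#' quaternion is renormalized at every step. Euler angles are extracted from
#' the rotated frame diagonal via [euler_angles()].
#'
#' @param gyro,accel n x 3 series (rad/s, m/s^2); `mag` optional n x 3 (uT).
#' @param cfg a [filter_config()] (uses `sample_rate`, `gd_step`).
#' @param q0 initial unit quaternion (w, x, y, z).
#' @param reference_field world-frame magnetic reference (uT); its full 3-D
#'   direction anchors yaw (NULL disables the magnetic correction).
#' @return an `orientation_state`: `q` (n x 4 unit quaternions) and `euler`
#'   (n x 3 matrix of Axz, Ayz, Axy in (-pi, pi]).
#' @export
fuse_orientation <- function(gyro, accel, mag = NULL, cfg = filter_config(),
                             q0 = q_identity(),
                             reference_field = MAG_REFERENCE) {
  gyro <- as.matrix(gyro); accel <- as.matrix(accel)
  assert_that(!anyNA(gyro) && !anyNA(accel) && (is.null(mag) || !anyNA(mag)),
              "NaN/NA in fusion inputs")
  assert_that(nrow(gyro) == nrow(accel), "gyro/accel not time-aligned")
  assert_that(abs(q_norm(q0) - 1) < 1e-9, "q0 must be a unit quaternion")
  n <- nrow(gyro)
  dt <- 1 / cfg$sample_rate
  ref_unit <- if (!is.null(reference_field)) {
    rn <- sqrt(sum(vec3(reference_field)^2))
    if (rn > 0) vec3(reference_field) / rn else NULL
  } else NULL
  q <- matrix(0, n, 4)
  cur <- q0
  for (k in seq_len(n)) {
    qdot <- 0.5 * q_mul(cur, c(0, gyro[k, ]))
    if (cfg$gd_step > 0) {
      an <- sqrt(sum(accel[k, ]^2))
      if (an > 0) {
        m_hat <- if (!is.null(mag)) {
          mn <- sqrt(sum(mag[k, ]^2))
          if (mn > 0) mag[k, ] / mn else NULL
        } else NULL
        grad <- madgwick_gradient(cur, accel[k, ] / an, m_hat, ref_unit)
        qdot <- qdot - cfg$gd_step * grad
      }
    }
    cur <- q_normalize(cur + qdot * dt)
    q[k, ] <- cur
  }
  diag_ref <- c(1, 1, 1) / sqrt(3)
  euler <- t(vapply(seq_len(n), function(k) {
    euler_angles(q_sensor_to_world(q[k, ], diag_ref))
  }, numeric(3)))
  colnames(euler) <- c("Axz", "Ayz", "Axy")
  structure(list(q = q, euler = euler), class = "orientation_state")
}

#' Euler angles of a 3-vector
#'
#' The three plane angles of a direction vector: Axz = atan2(z, x),
#' Ayz = atan2(z, y), Axy = atan2(y, x). Scale-invariant; the zero vector is
#' rejected because atan2(0, 0) is undefined by contract.
#'
#' @param v non-zero numeric 3-vector.
#' @return named numeric vector (Axz, Ayz, Axy), each in (-pi, pi].
#' @export
euler_angles <- function(v) {
  v <- vec3(v)
  assert_that(any(v != 0), "euler_angles is undefined for the zero vector")
  c(Axz = atan2(v[3], v[1]), Ayz = atan2(v[3], v[2]), Axy = atan2(v[2], v[1]))
}

#' Run the full IMU filtration chain on one recording
#'
#' Butterworth split and combined channel norm on the accelerometer, gravity
#' estimation (from a stationary lying interval when present, otherwise from
#' the lowest-magnitude second of data), DWT denoising of the gyroscope,
#' quaternion fusion, gravity removal and hard-iron magnetic correction.
#'
#' @param rec an `mm_recording` (or a list with `$imu` in the same layout).
#' @param cfg a [filter_config()]; its `sample_rate` is overridden by the
#'   recording's.
#' @return list with `time_s`, `lin_acc`, `gyro`, `mag`, `norm`, `orient`.
#' @export
preprocess_imu <- function(rec, cfg = filter_config()) {
  imu <- rec$imu
  cfg$sample_rate <- rec$script$sample_rate_imu
  accel <- as.matrix(imu[, c("ax", "ay", "az")])
  gyro <- as.matrix(imu[, c("gx", "gy", "gz")])
  mag <- as.matrix(imu[, c("mx", "my", "mz")])

  lpf <- sapply(1:3, function(j) butterworth_split(accel[, j], cfg)$low)
  hpf <- sapply(1:3, function(j) butterworth_split(accel[, j], cfg)$high)
  nrm <- channel_norm(lpf, hpf, cfg$norm_mode)

  labels <- rec$truth$imu_labels
  stat <- which(labels == "lying_down")
  if (length(stat) < cfg$sample_rate) {
    # fall back: the quietest 1-s span by norm of the high-pass residual
    w <- round(cfg$sample_rate)
    act <- stats::filter(rowSums(hpf^2), rep(1 / w, w), sides = 2)
    ctr <- which.min(act)
    stat <- max(1, ctr - w %/% 2):min(nrow(accel), ctr + w %/% 2)
  }
  g <- estimate_gravity(accel[stat, , drop = FALSE])

  gyro_dn <- sapply(1:3, function(j) dwt_denoise(gyro[, j], cfg))
  # constant gyro bias is estimated over the stationary span, but only
  # subtracted when that span is actually still (fallback windows inside a
  # moving recording would inject a spurious offset)
  if (max(apply(gyro_dn[stat, , drop = FALSE], 2, stats::sd)) < 0.05) {
    gyro_dn <- gyro_dn - matrix(colMeans(gyro_dn[stat, , drop = FALSE]),
                                nrow(gyro_dn), 3, byrow = TRUE)
  }
  orient <- fuse_orientation(gyro_dn, lpf, mag, cfg)
  lin_acc <- remove_gravity(accel, g, orient)
  mag_clean <- remove_magnetic_error(mag, MAG_REFERENCE, orient)
  list(time_s = imu$time_s, lin_acc = lin_acc, gyro = gyro_dn,
       mag = mag_clean, norm = nrm, orient = orient, gravity = g)
}

#' Pass-through moving-average baseline (ablation of the quaternion filter)
#'
#' Smooths every channel with a centred 5-sample moving average; no gravity
#' removal, no wavelet denoising, no orientation fusion (identity
#' orientation). Used as the "filtration novelty off" arm of ablation runs.
#'
#' @param rec an `mm_recording`. @param k moving-average width (odd).
#' @return same layout as [preprocess_imu()].
#' @export
preprocess_imu_baseline <- function(rec, k = 5) {
  imu <- rec$imu
  ma <- function(x) {
    y <- stats::filter(x, rep(1 / k, k), sides = 2)
    y[is.na(y)] <- x[is.na(y)]
    as.numeric(y)
  }
  accel <- sapply(c("ax", "ay", "az"), function(cn) ma(imu[[cn]]))
  gyro <- sapply(c("gx", "gy", "gz"), function(cn) ma(imu[[cn]]))
  mag <- sapply(c("mx", "my", "mz"), function(cn) ma(imu[[cn]]))
  n <- nrow(imu)
  q <- matrix(rep(q_identity(), n), n, 4, byrow = TRUE)
  euler <- matrix(atan2(1, 1), n, 3)
  list(time_s = imu$time_s, lin_acc = accel, gyro = gyro, mag = mag,
       norm = row_norms(accel),
       orient = structure(list(q = q, euler = euler),
                          class = "orientation_state"),
       gravity = NULL)
}
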