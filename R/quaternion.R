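#' Quaternion utilities
#'
#' Unit quaternions in (w, x, y, z) order represent the rotation from the
#' sensor frame to the world frame. All helpers operate on length-4 numeric
#' vectors or n x 4 matrices (one quaternion per row).
#'
#' @name quaternion
#' @keywords internal
NULL

q_identity <- function() c(1, 0, 0, 0)

q_norm <- function(q) sqrt(sum(q^2))

q_normalize <- function(q) {
  n <- q_norm(q)
  assert_that(n > 0, "cannot normalize a zero quaternion")
  q / n
}

q_conj <- function(q) c(q[1], -q[2], -q[3], -q[4])

# Hamilton product p * q
q_mul <- function(p, q) {
  c(p[1] * q[1] - p[2] * q[2] - p[3] * q[3] - p[4] * q[4],
    p[1] * q[2] + p[2] * q[1] + p[3] * q[4] - p[4] * q[3],
    p[1] * q[3] - p[2] * q[4] + p[3] * q[1] + p[4] * q[2],
    p[1] * q[4] + p[2] * q[3] - p[3] * q[2] + p[4] * q[1])
}

q_from_axis_angle <- function(axis, angle) {
  axis <- vec3(axis)
  n <- sqrt(sum(axis^2))
  assert_that(n > 0, "rotation axis must be non-zero")
  axis <- axis / n
  c(cos(angle / 2), sin(angle / 2) * axis)
}

# 3x3 rotation matrix (sensor -> world) of a unit quaternion
q_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Rotate a world-frame vector into the sensor frame (R^T v)
q_world_to_sensor <- function(q, v) as.numeric(crossprod(q_to_matrix(q), vec3(v)))

# Rotate a sensor-frame vector into the world frame (R v)
q_sensor_to_world <- function(q, v) as.numeric(q_to_matrix(q) %*% vec3(v))

# Smallest rotation angle (radians) between two unit quaternions
q_angle_between <- function(p, q) {
  d <- abs(sum(p * q))
  2 * acos(min(1, d))
}
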