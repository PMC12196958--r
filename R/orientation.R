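# quaternion helpers: q = c(w, x, y, z), unit norm, body-to-navigation (NED)

quat_mult <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_rotvec <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(c(1, v / 2))
  c(cos(ang / 2), sin(ang / 2) * v / ang)
}

quat_normalize <- function(q) q / sqrt(sum(q^2))

# rotation matrix R such that v_nav = R %*% v_body
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# intrinsic Z-Y-X (yaw-pitch-roll) Euler angles in degrees, NED convention
quat_to_euler <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2))
  sp <- 2 * (w * y - z * x)
  sp <- max(-1, min(1, sp))
  pitch <- asin(sp)
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2))
  c(roll = roll, pitch = pitch, yaw = yaw) * 180 / pi
}

skew3 <- function(v) {
  matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

# analysis frame (si, ml, ap) -> NED body frame: north = ap (forward),
# east = -ml (ml is positive left), down = -si (si is positive up)
to_ned <- function(mat) {
  cbind(n = mat[, "ap"], e = -mat[, "ml"], d = -mat[, "si"])
}

#' Estimate sensor orientation with an error-state Kalman filter
#'
#' Fuses gyroscope propagation with accelerometer gravity observations in a
#' quaternion error-state Kalman filter operating in the north-east-down
#' (NED) navigation frame. Roll and pitch are observable from gravity; yaw is
#' obtained by gyro integration alone (no magnetometer), initialized to zero
#' at trial start, so headings are relative to the initial heading - which is
#' exactly what yaw-threshold turn segmentation needs.
#'
#' Accelerometer updates are gated: samples whose specific-force norm is far
#' from gravity (strong linear acceleration or free-fall-like spans) are
#' skipped and the filter coasts on the gyro.
#'
#' @param trial a gap-filled [imu_trial()].
#' @param gyro_noise gyro white-noise density, rad/s/sqrt(Hz) (default 0.01).
#' @param accel_noise accelerometer direction noise, unitless on the gravity
#'   unit vector (default 0.1).
#' @param init_cov initial attitude error covariance, rad^2 (default 1e-4).
#' @param accel_gate relative deviation of the accelerometer norm from
#'   gravity beyond which the update is skipped (default 0.05).
#' @return an `orientation_track` list: `quaternion` (n x 4, unit,
#'   body-to-NED), `euler` (n x 3, roll/pitch/yaw in degrees, yaw unwrapped),
#'   `yaw_rate` (deg/s, from [yaw_rate()]), `fs`.
#' @export
estimate_orientation <- function(trial, gyro_noise = 0.01, accel_noise = 0.1,
                                 init_cov = 1e-4, accel_gate = 0.05) {
  if (anyNA(trial$accel) || anyNA(trial$gyro)) {
    stop("trial contains missing samples; run fill_gaps() first", call. = FALSE)
  }
  acc <- to_ned(trial$accel)
  gyr <- to_ned(trial$gyro) * pi / 180   # rad/s, body rates
  n <- trial$n
  dt <- 1 / trial$fs

  # initialize roll/pitch from the first accelerometer sample, yaw = 0
  a0 <- acc[1L, ]
  roll0 <- atan2(-a0[2], -a0[3])
  pitch0 <- atan2(a0[1], sqrt(a0[2]^2 + a0[3]^2))
  q <- quat_mult(quat_from_rotvec(c(0, pitch0, 0)),
                 quat_from_rotvec(c(roll0, 0, 0)))
  q <- quat_normalize(q)

  P <- diag(init_cov, 3)
  Q <- diag(gyro_noise^2 * dt, 3)
  Rm <- diag(accel_noise^2, 3)
  quats <- matrix(NA_real_, n, 4L)
  g_ref <- c(0, 0, -1)   # direction of specific force at rest, nav frame

  for (k in seq_len(n)) {
    if (k > 1L) {
      q <- quat_normalize(quat_mult(q, quat_from_rotvec(gyr[k, ] * dt)))
      P <- P + Q
    }
    a <- acc[k, ]
    nrm <- sqrt(sum(a^2))
    if (abs(nrm - .GRAVITY) <= accel_gate * .GRAVITY && nrm > 0) {
      Rot <- quat_to_matrix(q)
      pred <- as.numeric(crossprod(Rot, g_ref))   # R^T g_ref
      z <- a / nrm
      H <- skew3(pred)
      S <- H %*% P %*% t(H) + Rm
      Kk <- P %*% t(H) %*% solve(S)
      dth <- as.numeric(Kk %*% (z - pred))
      q <- quat_normalize(quat_mult(q, quat_from_rotvec(dth)))
      P <- (diag(3) - Kk %*% H) %*% P
    }
    quats[k, ] <- q
  }
  euler <- t(apply(quats, 1L, quat_to_euler))
  colnames(euler) <- c("roll", "pitch", "yaw")
  euler[, "yaw"] <- unwrap_deg(euler[, "yaw"])
  track <- structure(
    list(quaternion = quats, euler = euler, fs = trial$fs),
    class = "orientation_track"
  )
  track$yaw_rate <- yaw_rate(track)
  track
}

#' @export
print.orientation_track <- function(x, ...) {
  cat(sprintf("<orientation_track> %d samples @ %g Hz, yaw range [%.1f, %.1f] deg\n",
              nrow(x$quaternion), x$fs, min(x$euler[, "yaw"]),
              max(x$euler[, "yaw"])))
  invisible(x)
}

#' Yaw rate from an orientation track
#'
#' Central-difference derivative of the unwrapped yaw angle (one-sided
#' stencils at the series ends). An optional moving-average smoother is
#' available but off by default.
#'
#' @param track an [estimate_orientation()] result, or a numeric yaw series
#'   in degrees (then `fs` must be given).
#' @param fs sampling rate in Hz (taken from the track when omitted).
#' @param smooth_samples odd moving-average length; 0 disables (default).
#' @return yaw rate in deg/s, same length as the yaw series.
#' @export
yaw_rate <- function(track, fs = NULL, smooth_samples = 0L) {
  if (inherits(track, "orientation_track")) {
    yaw <- track$euler[, "yaw"]
    if (is.null(fs)) fs <- track$fs
  } else {
    yaw <- as.numeric(track)
    if (is.null(fs)) stop("fs required for a bare yaw series", call. = FALSE)
  }
  yaw <- unwrap_deg(yaw)
  rate <- discrete_gradient(yaw, h = 1 / fs)
  if (smooth_samples >= 3L) {
    sm <- stats::filter(rate, rep(1 / smooth_samples, smooth_samples), sides = 2L)
    rate <- ifelse(is.na(sm), rate, as.numeric(sm))
  }
  rate
}
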