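# Kinematic channel derivation ----------------------------------------------
#
# From one sensor recording the pipeline derives:
#   acc_x/y/z, gyro_x/y/z      raw sensor-frame streams
#   acc_vert, acc_horiz        globally resolved movement acceleration
#                              (gravity removed; horizontal = planar norm)
#   angle_xv/yv/zv             angle of each sensor axis to the vertical (deg)
#   swing, twist               (cannon sensors only) limb rotation angles
# giving 13 channels for cannon sensors and 11 for all others.

NONCANNON_CHANNELS <- c("acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z",
                        "acc_vert", "acc_horiz", "angle_xv", "angle_yv", "angle_zv")
CANNON_CHANNELS <- c(NONCANNON_CHANNELS, "swing", "twist")

# global linear (movement) acceleration, T x 3: R(q) acc - g zhat
global_linear_acceleration <- function(rec) {
  bad <- abs(quat_norm(rec$quat) - 1) > QUAT_NORM_TOL
  if (any(bad)) stop("non-unit quaternion in recording")
  a_g <- quat_rotate(rec$quat, rec$acc)
  a_g[, 3] <- a_g[, 3] - GRAVITY
  a_g
}

#' Resolve acceleration in the global frame
#'
#' Rotates the sensor-frame accelerometer stream into the global frame,
#' removes gravity, and returns the vertical component and the (non-negative)
#' norm of the horizontal-plane component. A static sensor therefore reads
#' zero in both channels regardless of its attitude.
#'
#' @param rec a [sensor_recording()]
#' @return list with numeric vectors `acc_vert` and `acc_horiz` (m/s^2)
#' @export
resolve_global_acceleration <- function(rec) {
  a_g <- global_linear_acceleration(rec)
  list(
    acc_vert = a_g[, 3],
    acc_horiz = sqrt(a_g[, 1]^2 + a_g[, 2]^2)
  )
}

#' Angle of each sensor axis to the earth vertical
#'
#' For axis i, `angle_iv = acos((R(q) e_i) . zhat)` in degrees, unsigned,
#' in \[0, 180\].
#'
#' @param rec a [sensor_recording()]
#' @return list with numeric vectors `angle_xv`, `angle_yv`, `angle_zv` (deg)
#' @export
axis_vertical_angles <- function(rec) {
  bad <- abs(quat_norm(rec$quat) - 1) > QUAT_NORM_TOL
  if (any(bad)) stop("non-unit quaternion in recording")
  out <- lapply(1:3, function(i) {
    e <- c(0, 0, 0); e[i] <- 1
    z <- quat_rotate(rec$quat, e)[, 3]
    deg(acos(clamp(z, -1, 1)))
  })
  names(out) <- c("angle_xv", "angle_yv", "angle_zv")
  out
}

#' Swing-twist decomposition of a limb sensor's orientation
#'
#' The attitude relative to a reference (default: the chordal mean attitude of
#' the passage, making the angles drift-free) is factored as
#' `q_rel = q_swing * q_twist`, where `q_twist` rotates about the limb's
#' longitudinal axis (sensor x by mounting convention) and `q_swing` about an
#' axis orthogonal to it. Twist is signed by the right-hand rule about
#' `+twist_axis`; swing is signed by the projection of its rotation axis on
#' the lateral axis (sensor y), ties resolved to positive.
#'
#' The degenerate case of a 180-degree rotation exactly orthogonal to the
#' twist axis (twist undefined) yields twist 0 and a QC flag.
#'
#' @param rec a [sensor_recording()]
#' @param twist_axis unit vector in the sensor frame (default `c(1, 0, 0)`)
#' @param reference 1 x 4 reference quaternion; default the mean attitude
#' @param lateral_axis sensor-frame axis used to sign the swing angle
#' @return list with numeric vectors `swing`, `twist` (degrees, signed),
#'   matrices `q_swing`, `q_twist` (for recomposition checks), and a logical
#'   `degenerate` flag vector
#' @export
swing_twist <- function(rec, twist_axis = c(1, 0, 0), reference = NULL,
                        lateral_axis = c(0, 1, 0)) {
  twist_axis <- twist_axis / sqrt(sum(twist_axis^2))
  q <- rec$quat
  reference <- reference %||% quat_mean(q)
  q_rel <- quat_canonical(quat_multiply(quat_conjugate(as_quat(reference)), q))
  n <- nrow(q_rel)

  # projection of the rotation's vector part onto the twist axis
  p <- q_rel[, 2:4, drop = FALSE] %*% twist_axis
  tw <- cbind(q_rel[, 1], p %*% t(twist_axis))
  tw_norm <- sqrt(rowSums(tw^2))
  degenerate <- tw_norm < 1e-12
  tw_unit <- tw
  tw_unit[!degenerate, ] <- tw[!degenerate, ] / tw_norm[!degenerate]
  tw_unit[degenerate, ] <- rep(c(1, 0, 0, 0), each = sum(degenerate))

  q_swing <- quat_multiply(q_rel, quat_conjugate(tw_unit))

  twist_angle <- 2 * atan2(as.numeric(p), q_rel[, 1])
  twist_angle[degenerate] <- 0
  # wrap to (-pi, pi]
  twist_angle <- ((twist_angle + pi) %% (2 * pi)) - pi

  sw_vec <- q_swing[, 2:4, drop = FALSE]
  sw_norm <- sqrt(rowSums(sw_vec^2))
  swing_angle <- 2 * atan2(sw_norm, q_swing[, 1])
  sgn <- sign(sw_vec %*% lateral_axis)
  sgn[sgn == 0] <- 1
  swing_angle <- swing_angle * as.numeric(sgn)

  list(
    swing = deg(swing_angle), twist = deg(twist_angle),
    q_swing = q_swing, q_twist = tw_unit, degenerate = degenerate
  )
}

#' Derive the full kinematic channel set of a sensor recording
#'
#' Assembles the raw sensor-frame accelerations and angular velocities, the
#' globally resolved vertical/horizontal accelerations, the three
#' axis-to-vertical angles and, for cannon sensors, the swing and twist
#' angles: 13 channels for cannon locations, 11 otherwise.
#'
#' @param rec a [sensor_recording()]
#' @return an object of class `channel_set`: list with `location`, `fs` and
#'   `channels` (named list of equal-length numeric vectors)
#' @export
derive_channels <- function(rec) {
  glob <- resolve_global_acceleration(rec)
  ang <- axis_vertical_angles(rec)
  channels <- list(
    acc_x = rec$acc[, 1], acc_y = rec$acc[, 2], acc_z = rec$acc[, 3],
    gyro_x = rec$gyro[, 1], gyro_y = rec$gyro[, 2], gyro_z = rec$gyro[, 3],
    acc_vert = glob$acc_vert, acc_horiz = glob$acc_horiz,
    angle_xv = ang$angle_xv, angle_yv = ang$angle_yv, angle_zv = ang$angle_zv
  )
  if (is_cannon(rec$location)) {
    st <- swing_twist(rec)
    channels$swing <- st$swing
    channels$twist <- st$twist
  }
  expected <- if (is_cannon(rec$location)) CANNON_CHANNELS else NONCANNON_CHANNELS
  stopifnot(identical(names(channels), expected))
  structure(
    list(location = rec$location, fs = rec$fs, channels = channels),
    class = "channel_set"
  )
}

#' @export
as.data.frame.channel_set <- function(x, ...) {
  n <- length(x$channels[[1]])
  cbind(data.frame(t = (seq_len(n) - 1) / x$fs), as.data.frame(x$channels))
}

#' Write a channel set to CSV (one column per channel, plus time)
#' @param cs a `channel_set`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_channel_set <- function(cs, path) {
  utils::write.csv(as.data.frame(cs), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.channel_set <- function(x, ...) {
  cat("<channel_set> ", location_key(x$location), ": ",
      length(x$channels), " channels x ", length(x$channels[[1]]),
      " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}
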