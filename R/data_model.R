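# Data model ----------------------------------------------------------------
#
# A recording session holds, for one horse / gait / run, one or more corridor
# passages; each passage is a set of time-synchronized per-sensor recordings.

LOCATION_CODES <- c(
  FH = "forehead", PO = "poll", WI = "withers", ST = "sternum",
  SA = "sacrum", FC = "forelimb-cannon", HC = "hindlimb-cannon"
)
CANNON_CODES <- c("FC", "HC")
QUAT_NORM_TOL <- 1e-6

#' Sensor location descriptor
#'
#' Seven anatomical sites carry sensors: forehead (FH), poll (PO), withers
#' (WI), sternum (ST), sacrum (SA) on the midline, and the forelimb (FC) and
#' hindlimb (HC) cannons, which exist on the left and right sides.
#'
#' @param code location code, one of `"FH"`, `"PO"`, `"WI"`, `"ST"`, `"SA"`,
#'   `"FC"`, `"HC"`
#' @param side `"left"`, `"right"` or `"midline"`; cannon sensors must be
#'   left or right, all others midline (the default is inferred)
#' @return an object of class `sensor_location`
#' @export
sensor_location <- function(code, side = NULL) {
  code <- match.arg(code, names(LOCATION_CODES))
  if (is.null(side)) side <- if (code %in% CANNON_CODES) "left" else "midline"
  side <- match.arg(side, c("left", "right", "midline"))
  if (code %in% CANNON_CODES && side == "midline")
    stop("cannon sensors (", code, ") must carry side 'left' or 'right'")
  if (!(code %in% CANNON_CODES) && side != "midline")
    stop("sensor ", code, " is a midline location")
  structure(list(code = code, side = side), class = "sensor_location")
}

#' @export
format.sensor_location <- function(x, ...) location_key(x)

#' @export
print.sensor_location <- function(x, ...) {
  cat("<sensor_location> ", location_key(x), " (", LOCATION_CODES[[x$code]], ")\n", sep = "")
  invisible(x)
}

#' Compact key for a sensor location ("ST", "FC_left", ...)
#' @param loc a `sensor_location`
#' @return character scalar
#' @export
location_key <- function(loc) {
  if (loc$side == "midline") loc$code else paste(loc$code, loc$side, sep = "_")
}

#' Parse a location key back into a `sensor_location`
#' @param key character scalar as produced by [location_key()]
#' @return a `sensor_location`
#' @export
parse_location_key <- function(key) {
  parts <- strsplit(key, "_", fixed = TRUE)[[1]]
  if (!(parts[1] %in% names(LOCATION_CODES)))
    stop("unknown location code: ", parts[1])
  sensor_location(parts[1], if (length(parts) > 1) parts[2] else NULL)
}

is_cannon <- function(loc) loc$code %in% CANNON_CODES

#' One sensor's synchronized IMU streams
#'
#' @param location a [sensor_location()]
#' @param fs sampling rate in Hz (> 0, constant over the recording)
#' @param acc T x 3 specific force in the sensor frame, m/s^2 (includes
#'   gravity, as measured by the accelerometer)
#' @param gyro T x 3 angular velocity in the sensor frame, rad/s
#' @param quat T x 4 unit orientation quaternions, scalar-first, rotating
#'   sensor-frame vectors into the global frame (+Z up)
#' @return an object of class `sensor_recording`
#' @export
sensor_recording <- function(location, fs, acc, gyro, quat) {
  if (!inherits(location, "sensor_location")) stop("location must be a sensor_location")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  acc <- as.matrix(acc); gyro <- as.matrix(gyro); quat <- as.matrix(quat)
  dimnames(acc) <- dimnames(gyro) <- dimnames(quat) <- NULL
  key <- location_key(location)
  if (ncol(acc) != 3) stop("sensor ", key, ": acc must have 3 columns")
  if (ncol(gyro) != 3) stop("sensor ", key, ": gyro must have 3 columns")
  if (ncol(quat) != 4) stop("sensor ", key, ": quat must have 4 columns")
  n <- nrow(acc)
  if (nrow(gyro) != n || nrow(quat) != n)
    stop("sensor ", key, ": length mismatch between acc/gyro/quat streams")
  if (n < 2 * fs)
    stop("sensor ", key, ": recording shorter than 2 s (T = ", n, ", fs = ", fs, ")")
  bad <- abs(quat_norm(quat) - 1) > QUAT_NORM_TOL
  if (any(bad))
    stop("sensor ", key, ": non-unit quaternion at ", sum(bad), " sample(s)")
  structure(
    list(location = location, fs = fs, acc = acc, gyro = gyro, quat = quat),
    class = "sensor_recording"
  )
}

#' @export
print.sensor_recording <- function(x, ...) {
  cat("<sensor_recording> ", location_key(x$location), ": ",
      nrow(x$acc), " samples @ ", x$fs, " Hz\n", sep = "")
  invisible(x)
}

#' A recording session (one horse, gait and run)
#'
#' @param horse_id character identifier
#' @param gait `"trot"` or `"canter"`
#' @param run `"before"` or `"after"` (relative to the training session)
#' @param passages list of passages; each passage is a named list of
#'   [sensor_recording()] objects (names are location keys), all sharing the
#'   same length and sampling rate
#' @return an object of class `gait_session`
#' @export
gait_session <- function(horse_id, gait, run, passages) {
  gait <- match.arg(gait, c("trot", "canter"))
  run <- match.arg(run, c("before", "after"))
  if (!is.list(passages) || length(passages) < 1)
    stop("at least one passage is required")
  for (p in seq_along(passages)) {
    pas <- passages[[p]]
    if (!is.list(pas) || length(pas) < 1 || is.null(names(pas)))
      stop("passage ", p, ": must be a named list of sensor recordings")
    lens <- vapply(pas, function(r) nrow(r$acc), integer(1))
    fss <- vapply(pas, function(r) r$fs, numeric(1))
    if (length(unique(lens)) != 1)
      stop("passage ", p, ": sensors are not time-synchronized (unequal lengths)")
    if (length(unique(fss)) != 1)
      stop("passage ", p, ": sensors have unequal sampling rates")
    keys <- vapply(pas, function(r) location_key(r$location), character(1))
    if (!identical(unname(keys), names(pas)))
      stop("passage ", p, ": list names must match sensor location keys")
  }
  structure(
    list(horse_id = horse_id, gait = gait, run = run, passages = passages),
    class = "gait_session"
  )
}

#' @export
print.gait_session <- function(x, ...) {
  cat("<gait_session> horse ", x$horse_id, ", ", x$gait, ", ", x$run, ": ",
      length(x$passages), " passage(s), sensors: ",
      paste(names(x$passages[[1]]), collapse = ", "), "\n", sep = "")
  invisible(x)
}

session_fs <- function(session) session$passages[[1]][[1]]$fs
session_sensors <- function(session) names(session$passages[[1]])
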