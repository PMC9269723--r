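# Session container I/O ------------------------------------------------------
#
# A session is stored as one directory:
#   meta.json                      horse_id, gait, run, fs, sensors, passages
#   p<k>_<LOC>.csv                 per passage & sensor: t, ax, ay, az,
#                                  gx, gy, gz, qw, qx, qy, qz   (RFC-4180)
#   ground_truth.json              optional generator sidecar (test support)
#
# Indicator tables are flat CSVs with columns
#   horse, gait, sensor, side, channel, indicator, scope, run, value

REC_COLUMNS <- c("t", "ax", "ay", "az", "gx", "gy", "gz", "qw", "qx", "qy", "qz")
INDICATOR_COLUMNS <- c("horse", "gait", "sensor", "side", "channel",
                       "indicator", "scope", "run", "value")

#' Write a session to a directory container
#'
#' One CSV per passage and sensor plus a `meta.json`; if the session carries a
#' generator ground-truth attribute it is stored as a `ground_truth.json`
#' sidecar (stride times and generating global accelerations, intended for
#' testing only).
#'
#' @param session a [gait_session()]
#' @param path directory to create/write into
#' @param digits significant digits used for the CSV streams
#' @return `path`, invisibly
#' @export
write_session <- function(session, path, digits = 15) {
  if (!inherits(session, "gait_session")) stop("session must be a gait_session")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fs <- session_fs(session)
  meta <- list(
    horse_id = session$horse_id, gait = session$gait, run = session$run,
    fs = fs, n_passages = length(session$passages),
    sensors = session_sensors(session)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  for (p in seq_along(session$passages)) {
    for (key in names(session$passages[[p]])) {
      rec <- session$passages[[p]][[key]]
      n <- nrow(rec$acc)
      df <- data.frame(
        t = (seq_len(n) - 1) / fs,
        ax = rec$acc[, 1], ay = rec$acc[, 2], az = rec$acc[, 3],
        gx = rec$gyro[, 1], gy = rec$gyro[, 2], gz = rec$gyro[, 3],
        qw = rec$quat[, 1], qx = rec$quat[, 2], qy = rec$quat[, 3],
        qz = rec$quat[, 4]
      )
      df[] <- lapply(df, function(col) signif(col, digits))
      utils::write.csv(df, file.path(path, sprintf("p%d_%s.csv", p, key)),
                       row.names = FALSE)
    }
  }
  gt <- attr(session, "ground_truth")
  if (!is.null(gt)) {
    jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Load a session from a directory container
#'
#' Validates all recording invariants on load (stream presence, equal lengths,
#' unit quaternions, known location codes); a ground-truth sidecar is
#' reattached when present.
#'
#' @param path directory written by [write_session()]
#' @return a validated [gait_session()]
#' @export
read_session <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) stop("not a session container (missing meta.json): ", path)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  passages <- vector("list", meta$n_passages)
  for (p in seq_len(meta$n_passages)) {
    pas <- list()
    for (key in meta$sensors) {
      f <- file.path(path, sprintf("p%d_%s.csv", p, key))
      if (!file.exists(f))
        stop("sensor ", key, ", passage ", p, ": missing stream file ", basename(f))
      df <- utils::read.csv(f)
      missing_cols <- setdiff(REC_COLUMNS, names(df))
      if (length(missing_cols))
        stop("sensor ", key, ": missing stream column(s) ",
             paste(missing_cols, collapse = ", "))
      loc <- parse_location_key(key)
      pas[[key]] <- sensor_recording(
        loc, meta$fs,
        acc = as.matrix(df[, c("ax", "ay", "az")]),
        gyro = as.matrix(df[, c("gx", "gy", "gz")]),
        quat = as.matrix(df[, c("qw", "qx", "qy", "qz")])
      )
    }
    passages[[p]] <- pas
  }
  session <- gait_session(meta$horse_id, meta$gait, meta$run, passages)
  gt_file <- file.path(path, "ground_truth.json")
  if (file.exists(gt_file)) {
    attr(session, "ground_truth") <- jsonlite::read_json(
      gt_file, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  session
}

#' Write an indicator table
#'
#' @param records data.frame of indicator records with the columns
#'   `horse, gait, sensor, side, channel, indicator, scope, run, value`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_indicator_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0)
    stop("records must be a non-empty data.frame")
  missing_cols <- setdiff(INDICATOR_COLUMNS, names(records))
  if (length(missing_cols))
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[, INDICATOR_COLUMNS]
  key <- do.call(paste, c(records[, setdiff(INDICATOR_COLUMNS, "value")], sep = "|"))
  if (anyDuplicated(key))
    stop("duplicate indicator key(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read an indicator table written by [write_indicator_table()]
#' @param path CSV path
#' @return data.frame of indicator records
#' @export
read_indicator_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    horse = "character", gait = "character", sensor = "character",
    side = "character", channel = "character", indicator = "character",
    scope = "character", run = "character", value = "numeric"
  ))
  missing_cols <- setdiff(INDICATOR_COLUMNS, names(df))
  if (length(missing_cols))
    stop("indicator table missing column(s): ", paste(missing_cols, collapse = ", "))
  df
}
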