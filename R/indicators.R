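# From sessions to indicator records -----------------------------------------
#
# All sensors of a passage are segmented with the sternum-derived stride
# boundaries (single time base). Strides of a run are pooled across the
# run's passages into one group per (sensor, channel); similarity indicators
# are computed against the group's reference stride, smoothness indicators
# per stride on the raw-time samples and averaged per run.

#' Analysis-stage parameters
#'
#' Defaults are the pipeline's canonical values: 4th-order 3 Hz low-pass for
#' segmentation, 75%-of-period peak spacing, 100-point stride normalization,
#' 10 Hz SPARC cutoff.
#'
#' @param fc_filter segmentation low-pass cutoff, Hz
#' @param filter_order Butterworth order
#' @param min_sep minimum peak spacing as fraction of the period
#' @param n_points normalized stride length
#' @param fc_sparc SPARC cutoff frequency, Hz
#' @param sparc_pad SPARC zero-padding factor
#' @return named list of parameters
#' @export
analysis_params <- function(fc_filter = 3, filter_order = 4, min_sep = 0.75,
                            n_points = 100, fc_sparc = 10, sparc_pad = 4) {
  list(fc_filter = fc_filter, filter_order = filter_order, min_sep = min_sep,
       n_points = n_points, fc_sparc = fc_sparc, sparc_pad = sparc_pad)
}

#' Segment, normalize and summarize one session
#'
#' Runs segmentation on the filtered sternum vertical acceleration of each
#' passage, cuts every channel of every sensor into the resulting strides,
#' normalizes them to `n_points` samples, and computes per-stride smoothness
#' values. Passages are pooled.
#'
#' @param session a [gait_session()] (must include a sternum sensor `"ST"`)
#' @param params an [analysis_params()] list
#' @return list with `norm` (sensor -> channel -> stride matrix), `sparc`
#'   (sensor -> strides x channels matrix, including `gyro_norm`), `ldlj`
#'   (sensor -> per-stride values), `durations` (kept stride durations, s),
#'   and `qc` (per-passage [qc_report()]s)
#' @export
session_features <- function(session, params = analysis_params()) {
  if (!("ST" %in% session_sensors(session)))
    stop("segmentation requires a sternum sensor (ST) in every passage")
  fs <- session_fs(session)
  norm <- list(); sp <- list(); ld <- list()
  durations <- numeric(0); qc <- list()

  for (p in seq_along(session$passages)) {
    pas <- session$passages[[p]]
    acc_vert <- resolve_global_acceleration(pas$ST)$acc_vert
    filt <- lowpass_butterworth(acc_vert, fs, params$fc_filter, params$filter_order)
    b <- detect_strides(filt, fs, params$min_sep)
    w <- stride_windows(b)
    qc[[p]] <- qc_report(b, filt)
    kept <- w[w$keep, , drop = FALSE]
    if (nrow(kept) < 1) next
    durations <- c(durations, kept$duration)

    for (key in names(pas)) {
      rec <- pas[[key]]
      cs <- derive_channels(rec)
      if (is.null(norm[[key]])) norm[[key]] <- list()
      for (ch in names(cs$channels)) {
        series <- cs$channels[[ch]]
        rows <- t(vapply(seq_len(nrow(kept)), function(i)
          normalize_stride(series[kept$start[i]:(kept$end[i] - 1)], params$n_points),
          numeric(params$n_points)))
        norm[[key]][[ch]] <- rbind(norm[[key]][[ch]], rows)
      }
      spm <- sparc_channels(cs, kept, params$fc_sparc, params$sparc_pad)
      spm <- cbind(spm, gyro_norm = sparc_gyro_norm(rec, kept, params$fc_sparc,
                                                    params$sparc_pad))
      sp[[key]] <- rbind(sp[[key]], spm)
      ld[[key]] <- c(ld[[key]], ldlj_strides(rec, kept))
    }
  }
  if (!length(durations)) stop("no usable strides found in session")
  list(norm = norm, sparc = sp, ldlj = ld, durations = durations, qc = qc)
}

indicator_record <- function(horse, gait, key, channel, indicator, scope, run, value) {
  loc <- parse_location_key(key)
  data.frame(horse = horse, gait = gait, sensor = loc$code, side = loc$side,
             channel = channel, indicator = indicator, scope = scope,
             run = run, value = value)
}

#' Indicator records for one horse's before/after session pair
#'
#' @param before,after [gait_session()] objects for the same horse and gait
#' @param params an [analysis_params()] list
#' @return data.frame of indicator records (see [write_indicator_table()]):
#'   CC and RMSD per channel for scopes `intra_before`, `intra_after`,
#'   `inter`, `inter_rev`; per-run mean SPARC per channel (plus the angular
#'   velocity norm), per-run mean LDLJ-A of the acceleration vector, and the
#'   per-run mean stride duration
#' @export
session_pair_indicators <- function(before, after, params = analysis_params()) {
  stopifnot(before$horse_id == after$horse_id, before$gait == after$gait,
            before$run == "before", after$run == "after")
  horse <- before$horse_id; gait <- before$gait
  fb <- session_features(before, params)
  fa <- session_features(after, params)

  out <- list()
  for (key in intersect(names(fb$norm), names(fa$norm))) {
    for (ch in names(fb$norm[[key]])) {
      gb <- fb$norm[[key]][[ch]]; ga <- fa$norm[[key]][[ch]]
      if (nrow(gb) < 2 || nrow(ga) < 2)
        stop("fewer than 2 strides for ", key, "/", ch)
      ri <- run_indicators(build_stride_group(gb), build_stride_group(ga))
      out[[length(out) + 1]] <- indicator_record(
        horse, gait, key, ch, ri$indicator, ri$scope, NA_character_, ri$value)
    }
    for (run in c("before", "after")) {
      spm <- if (run == "before") fb$sparc[[key]] else fa$sparc[[key]]
      ldv <- if (run == "before") fb$ldlj[[key]] else fa$ldlj[[key]]
      out[[length(out) + 1]] <- indicator_record(
        horse, gait, key, colnames(spm), "SPARC", run, run, colMeans(spm))
      out[[length(out) + 1]] <- indicator_record(
        horse, gait, key, "acc_vector", "LDLJ", run, run,
        mean(ldv, na.rm = TRUE))
    }
  }
  out[[length(out) + 1]] <- indicator_record(
    horse, gait, "ST", "stride", "stride_duration", c("before", "after"),
    c("before", "after"), c(mean(fb$durations), mean(fa$durations)))
  records <- do.call(rbind, out)
  attr(records, "qc") <- data.frame(
    horse = horse, gait = gait,
    run = rep(c("before", "after"), c(length(fb$qc), length(fa$qc))),
    passage = c(seq_along(fb$qc), seq_along(fa$qc)),
    period_cv = vapply(c(fb$qc, fa$qc), `[[`, numeric(1), "period_cv"),
    verdict = vapply(c(fb$qc, fa$qc), `[[`, character(1), "verdict")
  )
  records
}

#' Indicator records for a whole herd
#'
#' @param herd list of `list(horse_id, before, after)` entries, as produced
#'   by [generate_herd()] or [read_herd()]
#' @param params an [analysis_params()] list
#' @return combined indicator record data.frame
#' @export
herd_indicators <- function(herd, params = analysis_params()) {
  per_horse <- lapply(herd, function(entry)
    session_pair_indicators(entry$before, entry$after, params))
  records <- do.call(rbind, per_horse)
  attr(records, "qc") <- do.call(rbind, lapply(per_horse, attr, "qc"))
  records
}
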