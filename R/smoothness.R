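# Movement smoothness metrics ------------------------------------------------
#
# SPARC: negative arc length of the max-normalized Fourier magnitude spectrum
# over [0, fc], with the frequency axis scaled by 1/fc. More negative = less
# smooth. The frequency-axis terms alone contribute an arc length of exactly
# 1, so SPARC <= -1 for every signal.
#
# LDLJ-A: negative log of the dimensionless time-integral of squared jerk of
# the gravity-free acceleration vector,
#   LDLJ = -ln( (t2 - t1) / apeak^2 * integral ||da/dt||^2 dt ),
# where apeak is the peak acceleration magnitude after removing the mean
# acceleration vector. More negative = less smooth.

#' Spectral arc length (SPARC) of a signal
#'
#' The magnitude spectrum is computed by FFT with zero-padding to the next
#' power of two at least `pad_factor` times the segment length (rectangular
#' window), normalized by its maximum, and its arc length is accumulated over
#' \[0, fc\] (with an interpolated endpoint exactly at fc):
#' `SPARC = -sum sqrt((df/fc)^2 + dV^2)`.
#'
#' A constant, non-zero signal concentrates all magnitude in the single DC
#' bin; this degenerate single-bin spectrum has no magnitude variation and
#' its arc length reduces to the frequency-axis term, giving SPARC exactly
#' -1 (flagged via the `"degenerate"` attribute). An identically zero signal
#' has an undefined normalized spectrum and raises an error.
#'
#' @param v numeric signal (length >= 8)
#' @param fs sampling rate, Hz (must exceed `2 * fc`)
#' @param fc spectral cutoff frequency, Hz (default 10)
#' @param pad_factor zero-padding factor (default 4)
#' @return SPARC value (dimensionless, <= -1)
#' @export
sparc <- function(v, fs, fc = 10, pad_factor = 4) {
  if (length(v) < 8) stop("signal too short for SPARC (need >= 8 samples)")
  if (fs <= 2 * fc) stop("cutoff above Nyquist (fs = ", fs, ", fc = ", fc, ")")
  if (all(v == 0)) stop("degenerate spectrum: signal is identically zero")
  if (stats::sd(v) == 0) return(structure(-1, degenerate = TRUE))
  nfft <- 2^ceiling(log2(pad_factor * length(v)))
  mag <- Mod(stats::fft(c(v, numeric(nfft - length(v)))))
  half <- nfft %/% 2 + 1
  mag <- mag[seq_len(half)]
  freqs <- (seq_len(half) - 1) * fs / nfft
  vhat <- mag / max(mag)
  -spectral_arc_length(freqs, vhat, fc)
}

# arc length of the piecewise-linear normalized spectrum over [0, fc] with
# the frequency axis scaled by 1/fc; interpolates an endpoint exactly at fc
spectral_arc_length <- function(freqs, vhat, fc) {
  if (max(freqs) < fc) stop("spectrum does not reach the cutoff frequency")
  keep <- freqs <= fc
  f_sel <- freqs[keep]
  v_sel <- vhat[keep]
  if (max(f_sel) < fc) {
    i <- sum(keep)
    v_fc <- vhat[i] + (vhat[i + 1] - vhat[i]) *
      (fc - freqs[i]) / (freqs[i + 1] - freqs[i])
    f_sel <- c(f_sel, fc)
    v_sel <- c(v_sel, v_fc)
  }
  sum(sqrt((diff(f_sel) / fc)^2 + diff(v_sel)^2))
}

#' Per-stride SPARC of the angular velocity norm
#'
#' @param rec a [sensor_recording()]
#' @param windows stride windows as returned by [stride_windows()] (only rows
#'   with `keep = TRUE` are used)
#' @param fc,pad_factor passed to [sparc()]
#' @return numeric vector, one SPARC value per kept stride
#' @export
sparc_gyro_norm <- function(rec, windows, fc = 10, pad_factor = 4) {
  gnorm <- sqrt(rowSums(rec$gyro^2))
  w <- windows[windows$keep, , drop = FALSE]
  vapply(seq_len(nrow(w)), function(i)
    as.numeric(sparc(gnorm[w$start[i]:(w$end[i] - 1)], rec$fs, fc, pad_factor)),
    numeric(1))
}

#' Log dimensionless jerk of the acceleration vector (LDLJ-A)
#'
#' The sensor-frame acceleration is resolved in the global frame with gravity
#' removed (same code path as [resolve_global_acceleration()]); jerk is
#' obtained by central differences and integrated by the trapezoidal rule
#' over the segment; `apeak` is the maximum acceleration magnitude after
#' removing the segment-mean acceleration vector.
#'
#' @param acc T x 3 sensor-frame acceleration, m/s^2
#' @param quat T x 4 sensor-to-global unit quaternions
#' @param fs sampling rate, Hz
#' @param segment numeric `c(t1, t2)` in seconds (relative to sample 1 at
#'   t = 0); default the whole recording
#' @return LDLJ-A value (dimensionless), or `NA` with attribute
#'   `"degenerate"` when `apeak` or the jerk integral is zero
#' @export
ldlj_a <- function(acc, quat, fs, segment = NULL) {
  acc <- as.matrix(acc); quat <- as.matrix(quat)
  n <- nrow(acc)
  segment <- segment %||% c(0, (n - 1) / fs)
  if (segment[2] <= segment[1]) stop("segment must satisfy t2 > t1")
  i1 <- round(segment[1] * fs) + 1
  i2 <- round(segment[2] * fs) + 1
  if (i1 < 1 || i2 > n) stop("segment outside the recording")
  if (i2 - i1 + 1 < 8) stop("segment too short for LDLJ (need >= 8 samples)")

  rec <- list(acc = acc[i1:i2, , drop = FALSE], quat = quat[i1:i2, , drop = FALSE])
  a_g <- global_linear_acceleration(rec)
  m <- nrow(a_g)
  a_c <- sweep(a_g, 2, colMeans(a_g))
  apeak <- max(sqrt(rowSums(a_c^2)))

  jerk <- a_g
  jerk[2:(m - 1), ] <- (a_g[3:m, ] - a_g[1:(m - 2), ]) * fs / 2
  jerk[1, ] <- (a_g[2, ] - a_g[1, ]) * fs
  jerk[m, ] <- (a_g[m, ] - a_g[m - 1, ]) * fs
  integral <- trapz_uniform(rowSums(jerk^2), fs)

  if (apeak == 0 || integral == 0)
    return(structure(NA_real_, degenerate = TRUE))
  duration <- (i2 - i1) / fs
  -log(duration / apeak^2 * integral)
}

#' Per-stride LDLJ-A of a sensor recording
#'
#' @param rec a [sensor_recording()]
#' @param windows stride windows from [stride_windows()] (kept rows only)
#' @return numeric vector, one LDLJ-A value per kept stride
#' @export
ldlj_strides <- function(rec, windows) {
  w <- windows[windows$keep, , drop = FALSE]
  vapply(seq_len(nrow(w)), function(i) {
    as.numeric(ldlj_a(rec$acc, rec$quat, rec$fs,
                      segment = c((w$start[i] - 1) / rec$fs,
                                  (w$end[i] - 1) / rec$fs)))
  }, numeric(1))
}

#' Per-stride SPARC of every channel in a channel set
#'
#' @param cs a `channel_set` from [derive_channels()]
#' @param windows stride windows from [stride_windows()] (kept rows only)
#' @param fc,pad_factor passed to [sparc()]
#' @return matrix: kept strides x channels
#' @export
sparc_channels <- function(cs, windows, fc = 10, pad_factor = 4) {
  w <- windows[windows$keep, , drop = FALSE]
  out <- sapply(cs$channels, function(ch) {
    vapply(seq_len(nrow(w)), function(i)
      as.numeric(sparc(ch[w$start[i]:(w$end[i] - 1)], cs$fs, fc, pad_factor)),
      numeric(1))
  })
  matrix(out, nrow = nrow(w), dimnames = list(NULL, names(cs$channels)))
}
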