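# Stride segmentation --------------------------------------------------------
#
# Strides are delimited by consecutive maxima of the low-pass filtered sternum
# vertical acceleration. Candidate local maxima are accepted greedily in
# amplitude-descending order subject to a spacing constraint: a candidate
# closer than 75% of the current period estimate to an accepted peak is
# rejected. The period estimate is initialized from the dominant spectral
# frequency in [0.5, 3] Hz and updated as the running median of accepted
# inter-peak intervals.

#' Zero-phase Butterworth low-pass filter
#'
#' 4th-order low-pass Butterworth with 3 Hz cutoff by default, applied
#' forward-backward (zero phase) so peak timing is not lagged; the effective
#' magnitude response is that of an 8th-order filter. Unit DC gain.
#'
#' @param x numeric signal
#' @param fs sampling rate, Hz
#' @param fc cutoff frequency, Hz (default 3)
#' @param order filter order (default 4)
#' @return filtered signal, same length
#' @export
lowpass_butterworth <- function(x, fs, fc = 3, order = 4) {
  if (fs <= 2 * fc) stop("cutoff above Nyquist (fs = ", fs, ", fc = ", fc, ")")
  if (length(x) <= 3 * order) stop("signal too short to filter")
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # filtfilt removes the mean-dependent edge transients poorly for large
  # offsets; filter around the mean and add it back (DC gain is 1 anyway)
  mu <- mean(x)
  signal::filtfilt(bf, x - mu) + mu
}

# dominant spectral frequency of a (mean-removed) signal, Hz
dominant_frequency <- function(x, fs) {
  n <- length(x)
  nfft <- 2^ceiling(log2(max(4 * n, 256)))
  mag <- Mod(stats::fft(c(x - mean(x), numeric(nfft - n))))[seq_len(nfft %/% 2)]
  freqs <- (seq_len(nfft %/% 2) - 1) * fs / nfft
  freqs[which.max(mag)]
}

#' Detect stride boundary peaks
#'
#' @param x low-pass filtered sternum vertical acceleration
#' @param fs sampling rate, Hz
#' @param min_sep_frac minimum inter-peak spacing as a fraction of the period
#'   estimate (default 0.75)
#' @param period_band frequency band (Hz) searched for the initial period
#' @return an object of class `stride_boundaries`: list with `peak_indices`
#'   (1-based, strictly increasing), `peak_times` (s), `periods` (s, between
#'   consecutive peaks), `flags` (per peak: `ok`, `edge_truncated`,
#'   `low_prominence`), `period_estimate` (s) and `fs`
#' @export
detect_strides <- function(x, fs, min_sep_frac = 0.75, period_band = c(0.5, 3)) {
  if (length(x) < 2 * fs) stop("need at least 2 s of signal")
  f_dom <- dominant_frequency(x, fs)
  if (f_dom < period_band[1] || f_dom > period_band[2])
    stop("no periodicity detected in [", period_band[1], ", ", period_band[2],
         "] Hz (dominant frequency ", signif(f_dom, 3), " Hz)")
  period0 <- 1 / f_dom

  n <- length(x)
  interior <- 2:(n - 1)
  is_max <- x[interior] > x[interior - 1] & x[interior] >= x[interior + 1]
  cand <- interior[is_max]
  if (length(cand) < 2) stop("fewer than 2 candidate peaks found")
  cand <- cand[order(x[cand], decreasing = TRUE)]

  accepted <- integer(0)
  period_est <- period0
  for (idx in cand) {
    if (length(accepted) == 0 ||
        all(abs(idx - accepted) > min_sep_frac * period_est * fs)) {
      accepted <- sort(c(accepted, idx))
      if (length(accepted) >= 2) {
        intervals <- diff(accepted) / fs
        valid <- intervals[intervals > 0.55 * period0 & intervals < 1.8 * period0]
        if (length(valid)) period_est <- stats::median(valid)
      }
    }
  }
  if (length(accepted) < 2) stop("fewer than 2 peaks accepted")

  # per-peak QC flags
  flags <- rep("ok", length(accepted))
  half <- 0.5 * period_est * fs
  flags[accepted < half | accepted > n - half] <- "edge_truncated"
  # prominence: height above the larger of the two adjacent valley minima
  prom <- vapply(seq_along(accepted), function(k) {
    left <- if (k == 1) 1 else accepted[k - 1]
    right <- if (k == length(accepted)) n else accepted[k + 1]
    x[accepted[k]] - max(min(x[left:accepted[k]]), min(x[accepted[k]:right]))
  }, numeric(1))
  low <- prom < 0.2 * stats::median(prom)
  flags[low & flags == "ok"] <- "low_prominence"

  periods <- diff(accepted) / fs
  stopifnot(all(periods > min_sep_frac * period_est | periods > min_sep_frac * period0))

  structure(
    list(peak_indices = accepted, peak_times = (accepted - 1) / fs,
         periods = periods, flags = flags, period_estimate = period_est,
         fs = fs, n_samples = n, min_sep_frac = min_sep_frac),
    class = "stride_boundaries"
  )
}

#' @export
print.stride_boundaries <- function(x, ...) {
  cat("<stride_boundaries> ", length(x$peak_indices), " peaks, period ~",
      signif(x$period_estimate, 3), " s (", sum(x$flags != "ok"),
      " flagged)\n", sep = "")
  invisible(x)
}

#' Stride windows from detected boundaries
#'
#' Each stride is the half-open sample interval between consecutive accepted
#' peaks. Strides bounded by an `edge_truncated` peak or with an interval
#' shorter than the spacing constraint are marked not keepable.
#'
#' @param b a `stride_boundaries` object
#' @return data.frame with columns `start`, `end` (1-based sample indices,
#'   half-open), `duration` (s), `flag`, `keep`
#' @export
stride_windows <- function(b) {
  k <- length(b$peak_indices) - 1
  if (k < 1) return(data.frame())
  flag <- character(k)
  for (i in seq_len(k)) {
    f1 <- b$flags[i]; f2 <- b$flags[i + 1]
    flag[i] <- if (b$periods[i] <= b$min_sep_frac * b$period_estimate) "short_period"
    else if (f1 == "edge_truncated" || f2 == "edge_truncated") "edge_truncated"
    else if (f1 == "low_prominence" || f2 == "low_prominence") "low_prominence"
    else "ok"
  }
  data.frame(
    start = b$peak_indices[-(k + 1)], end = b$peak_indices[-1],
    duration = b$periods, flag = flag, keep = flag == "ok"
  )
}

#' Automated segmentation quality report
#'
#' Surrogate for a manual check of the segmentation: per-stride flags, the
#' coefficient of variation of stride periods, and an overall verdict
#' (`"warn"` if the period CV exceeds 15% or any stride is flagged).
#'
#' @param b a `stride_boundaries` object
#' @param x the filtered signal the boundaries were detected on (unused
#'   beyond length checks; kept for report extensions)
#' @return list with `strides` (data.frame), `period_cv`, `n_ok`, `verdict`
#' @export
qc_report <- function(b, x = NULL) {
  w <- stride_windows(b)
  cv <- stats::sd(b$periods) / mean(b$periods)
  verdict <- if (cv > 0.15 || any(w$flag %in% c("short_period", "low_prominence")))
    "warn" else "pass"
  list(strides = w, period_cv = cv, n_ok = sum(w$flag == "ok"), verdict = verdict)
}
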