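# Synthetic gait generator ---------------------------------------------------
#
# Quasi-periodic multi-sensor IMU recordings are synthesized from harmonic
# series of the stride frequency. For each sensor a global kinematic
# acceleration and a smooth orientation trajectory are generated; the
# sensor-frame accelerometer stream is then the inverse-rotated
# (global acceleration + gravity) plus measurement noise, so the data are
# physically self-consistent: re-resolving the stored acceleration in the
# global frame and removing gravity recovers the generating signal exactly
# when noise is zero.

DEFAULT_SENSORS <- c("FH", "PO", "WI", "ST", "SA",
                     "FC_left", "FC_right", "HC_left", "HC_right")

# harmonic-1 amplitudes per location: global acceleration (m/s^2, X/Y/Z) and
# sensor-frame Euler oscillation (deg, roll/pitch/yaw). Body sensors move
# mostly vertically; limb sensors carry large accelerations and a wide
# swing (pitch) excursion so the swing-twist channels are informative.
LOCATION_WAVEFORMS <- list(
  FH = list(acc = c(2.5, 1.2, 3.5), euler = c(4, 6, 3)),
  PO = list(acc = c(2.5, 1.2, 4.0), euler = c(5, 6, 4)),
  WI = list(acc = c(1.8, 1.0, 4.5), euler = c(3, 3, 2)),
  ST = list(acc = c(2.5, 1.8, 8.0), euler = c(3, 4, 2)),
  SA = list(acc = c(2.5, 1.8, 7.0), euler = c(3, 4, 3)),
  FC = list(acc = c(14, 8, 20), euler = c(8, 35, 5)),
  HC = list(acc = c(12, 7, 18), euler = c(8, 35, 5))
)

#' Gait waveform template
#'
#' Defines, per sensor location, the harmonic series (amplitudes and phases of
#' harmonics 1..H of the stride frequency) generating the global acceleration
#' and the orientation oscillation. The sternum vertical acceleration uses
#' pure cosine harmonics (all phases zero) so its maxima fall exactly on the
#' stride boundaries - the generator's ground truth for segmentation.
#'
#' @param gait `"trot"` or `"canter"`
#' @param stride_freq stride frequency in Hz; defaults to 1.4 (trot) or
#'   1.8 (canter), typical equine values
#' @param n_harmonics number of harmonics H (>= 3)
#' @param decay geometric amplitude decay per harmonic
#' @return an object of class `gait_template`
#' @export
gait_template <- function(gait = c("trot", "canter"), stride_freq = NULL,
                          n_harmonics = 5, decay = 0.55) {
  gait <- match.arg(gait)
  stride_freq <- stride_freq %||% switch(gait, trot = 1.4, canter = 1.8)
  if (stride_freq <= 0) stop("stride_freq must be positive")
  if (n_harmonics < 3) stop("at least 3 harmonics are required")
  H <- n_harmonics
  locations <- list()
  for (i in seq_along(LOCATION_WAVEFORMS)) {
    code <- names(LOCATION_WAVEFORMS)[i]
    base <- LOCATION_WAVEFORMS[[code]]
    hfac <- decay^(seq_len(H) - 1)
    acc_amp <- outer(hfac, base$acc)
    euler_amp <- outer(hfac, rad(base$euler))
    # deterministic, location- and component-specific phases
    acc_phase <- outer(0.9 * (seq_len(H) - 1), rep(1, 3)) +
      outer(rep(1, H), 0.7 * (0:2)) + 0.4 * i
    euler_phase <- outer(1.1 * (seq_len(H) - 1), rep(1, 3)) +
      outer(rep(1, H), 0.5 * (0:2)) + 0.4 * i + 0.9
    if (code == "ST") acc_phase[, 3] <- 0  # segmentation anchor channel
    if (gait == "canter") {
      # lead-dependent pitch: stronger, phase-advanced pitching at canter
      euler_amp[, 2] <- euler_amp[, 2] * 1.4
      euler_phase[, 2] <- euler_phase[, 2] + 0.5
    }
    # limbs hang downward: sensor x (limb long axis) maps to global -Z
    mean_att <- if (code %in% CANNON_CODES)
      quat_from_axis_angle(c(0, 1, 0), pi / 2) else matrix(c(1, 0, 0, 0), 1)
    locations[[code]] <- list(
      acc_amp = acc_amp, acc_phase = acc_phase %% (2 * pi),
      euler_amp = euler_amp, euler_phase = euler_phase %% (2 * pi),
      mean_att = mean_att
    )
  }
  structure(
    list(gait = gait, stride_freq = stride_freq, n_harmonics = H,
         decay = decay, locations = locations),
    class = "gait_template"
  )
}

#' Training/fatigue perturbation knobs
#'
#' Each knob is dimensionless in \[0, 1\] and maps monotonically onto one
#' indicator family: `shape_delta` phase-shifts harmonics >= 2 (waveform
#' distortion, lowers inter-run CC), `amp_delta` scales amplitudes by
#' `1 + amp_delta` (raises inter-run RMSD), `roughness_delta` adds 8-12 Hz
#' band-limited noise with SD `delta` times the channel SD (degrades
#' SPARC/LDLJ smoothness). All zero is the null effect.
#'
#' @param shape_delta,amp_delta,roughness_delta numeric in \[0, 1\]
#' @return an object of class `fatigue_effect`
#' @export
fatigue_effect <- function(shape_delta = 0, amp_delta = 0, roughness_delta = 0) {
  for (v in c(shape_delta, amp_delta, roughness_delta))
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop("effect knobs must be scalars in [0, 1]")
  structure(
    list(shape_delta = shape_delta, amp_delta = amp_delta,
         roughness_delta = roughness_delta),
    class = "fatigue_effect"
  )
}

is_null_effect <- function(effect) {
  effect$shape_delta == 0 && effect$amp_delta == 0 && effect$roughness_delta == 0
}

#' Study-design parameters for a synthetic herd
#'
#' @param n_horses number of horses (>= 2; default 10, the study size)
#' @param passages_per_run corridor passages per run (default 2)
#' @param duration_s passage duration in seconds (must allow >= 2 strides)
#' @param fs sampling rate in Hz (default 128)
#' @param noise_acc_sd accelerometer noise SD, m/s^2
#' @param noise_gyro_sd gyroscope noise SD, rad/s
#' @param jitter_sd stride-to-stride timing jitter, as a fraction of the
#'   stride period (default 0.02)
#' @param seed integer RNG seed; all randomness derives from it
#' @param sensors character vector of location keys to simulate
#' @return an object of class `herd_spec`
#' @export
herd_spec <- function(n_horses = 10, passages_per_run = 2, duration_s = 8,
                      fs = 128, noise_acc_sd = 0.3, noise_gyro_sd = 0.05,
                      jitter_sd = 0.02, seed = 1, sensors = DEFAULT_SENSORS) {
  if (n_horses < 2) stop("n_horses must be >= 2")
  if (passages_per_run < 1) stop("passages_per_run must be >= 1")
  if (duration_s <= 0 || fs <= 0) stop("duration_s and fs must be positive")
  lapply(sensors, parse_location_key)  # validates keys
  structure(
    list(n_horses = n_horses, passages_per_run = passages_per_run,
         duration_s = duration_s, fs = fs, noise_acc_sd = noise_acc_sd,
         noise_gyro_sd = noise_gyro_sd, jitter_sd = jitter_sd,
         seed = as.integer(seed), sensors = sensors),
    class = "herd_spec"
  )
}

# 8-12 Hz band-limited noise scaled to a target SD (consumes the current RNG)
band_limited_noise <- function(n, fs, sd_target, band = c(8, 12)) {
  if (sd_target <= 0) return(numeric(n))
  w <- stats::rnorm(n)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, w)
  y * sd_target / stats::sd(y)
}

# jittered stride boundary times covering [0, duration]; returns the boundary
# vector (first element < 0) and the cumulative stride indices
stride_boundary_times <- function(period, duration, jitter_sd) {
  t0 <- 0.4 * period
  times <- t0
  while (times[length(times)] <= duration + period) {
    step <- period * max(0.2, 1 + stats::rnorm(1, 0, jitter_sd))
    times <- c(times, times[length(times)] + step)
  }
  pre <- t0 - period * max(0.2, 1 + stats::rnorm(1, 0, jitter_sd))
  c(pre, times)
}

#' Generate one synthetic session
#'
#' Builds `spec$passages_per_run` time-synchronized multi-sensor passages for
#' one horse and run. Horse-level waveform parameters (amplitude multipliers,
#' stride-frequency multiplier, phase offsets) are drawn from a substream
#' that depends only on `(spec$seed, horse_index)`, so the before and after
#' runs of a horse share the same underlying locomotion; passage-level
#' realizations (timing jitter, noise) are independent per run and passage.
#'
#' The returned session carries a `ground_truth` attribute with the true
#' stride boundary times and the generating global accelerations per sensor,
#' for oracle tests.
#'
#' @param template a [gait_template()]
#' @param effect a [fatigue_effect()]; apply the null effect for "before" runs
#' @param spec a [herd_spec()]
#' @param horse_id character identifier
#' @param run `"before"` or `"after"`
#' @param horse_index integer used to derive the horse's RNG substream
#' @return a [gait_session()] with a `ground_truth` attribute
#' @export
generate_session <- function(template, effect, spec, horse_id = "H01",
                             run = c("before", "after"), horse_index = 1) {
  run <- match.arg(run)
  if (!inherits(template, "gait_template")) stop("template must be a gait_template")
  if (!inherits(effect, "fatigue_effect")) stop("effect must be a fatigue_effect")
  if (!inherits(spec, "herd_spec")) stop("spec must be a herd_spec")
  if (spec$duration_s * template$stride_freq < 2)
    stop("duration too short for 2 strides at stride_freq = ", template$stride_freq)

  fs <- spec$fs
  n <- round(spec$duration_s * fs)
  tt <- (seq_len(n) - 1) / fs
  H <- template$n_harmonics

  # horse-level parameters: shared between runs of the same horse
  horse_seed <- derive_seed(spec$seed, horse_index)
  horse <- with_seed(horse_seed, {
    codes <- names(template$locations)
    list(
      amp_mult = stats::setNames(exp(stats::rnorm(length(codes), 0, 0.15)), codes),
      freq_mult = 1 + stats::rnorm(1, 0, 0.05),
      # per-location, per-component phase offsets on harmonics >= 2 only,
      # so the fundamental (and the sternum anchor) stays aligned
      phase_off = stats::setNames(lapply(codes, function(cd)
        stats::runif(3, -0.4, 0.4)), codes)
    )
  })

  f0 <- template$stride_freq * horse$freq_mult
  period <- 1 / f0
  run_idx <- if (run == "before") 1L else 2L

  passages <- vector("list", spec$passages_per_run)
  gt_passages <- vector("list", spec$passages_per_run)
  for (p in seq_len(spec$passages_per_run)) {
    pass_seed <- derive_seed(spec$seed, horse_index, run_idx, p)
    res <- with_seed(pass_seed, {
      bounds <- stride_boundary_times(period, spec$duration_s, spec$jitter_sd)
      phi <- stats::approx(bounds, 2 * pi * (seq_along(bounds) - 2), xout = tt)$y
      peak_times <- bounds[bounds >= 0 & bounds < spec$duration_s]

      sensors <- list()
      gt_acc <- list()
      for (key in spec$sensors) {
        loc <- parse_location_key(key)
        pars <- template$locations[[loc$code]]
        acc_amp <- pars$acc_amp * horse$amp_mult[[loc$code]]
        euler_amp <- pars$euler_amp
        acc_phase <- pars$acc_phase
        euler_phase <- pars$euler_phase
        # horse-specific waveform individuality (harmonics >= 2)
        if (H >= 2) {
          off <- horse$phase_off[[loc$code]]
          acc_phase[-1, ] <- acc_phase[-1, ] + rep(off, each = H - 1)
          euler_phase[-1, ] <- euler_phase[-1, ] + rep(off, each = H - 1)
          if (loc$code == "ST") acc_phase[, 3] <- pars$acc_phase[, 3]
        }
        # fatigue perturbations
        if (effect$shape_delta > 0 && H >= 2) {
          shift <- effect$shape_delta * seq_len(H)
          acc_phase[-1, ] <- acc_phase[-1, ] + shift[-1]
          euler_phase[-1, ] <- euler_phase[-1, ] + shift[-1]
        }
        acc_amp <- acc_amp * (1 + effect$amp_delta)

        mirror <- if (loc$side == "right") -1 else 1  # antiphase lateral motion
        a_global <- matrix(0, n, 3)
        roll <- pitch <- yaw <- numeric(n)
        for (h in seq_len(H)) {
          for (cmp in 1:3) {
            a_global[, cmp] <- a_global[, cmp] +
              acc_amp[h, cmp] * cos(h * phi + acc_phase[h, cmp] +
                                      if (cmp == 2) (mirror - 1) * pi / 2 else 0)
          }
          roll <- roll + euler_amp[h, 1] * cos(h * phi + euler_phase[h, 1])
          pitch <- pitch + mirror * euler_amp[h, 2] * cos(h * phi + euler_phase[h, 2])
          yaw <- yaw + euler_amp[h, 3] * cos(h * phi + euler_phase[h, 3])
        }
        if (effect$roughness_delta > 0) {
          for (cmp in 1:3) {
            a_global[, cmp] <- a_global[, cmp] + band_limited_noise(
              n, fs, effect$roughness_delta * stats::sd(a_global[, cmp]))
          }
        }

        q <- quat_normalize(quat_multiply(pars$mean_att,
                                          quat_from_euler(roll, pitch, yaw)))
        omega <- quat_angular_velocity(q, fs)
        if (effect$roughness_delta > 0) {
          for (cmp in 1:3) {
            omega[, cmp] <- omega[, cmp] + band_limited_noise(
              n, fs, effect$roughness_delta * stats::sd(omega[, cmp]))
          }
        }
        gvec <- matrix(c(0, 0, GRAVITY), 1)
        acc_sensor <- quat_rotate(quat_conjugate(q),
                                  a_global + gvec[rep(1, n), ])
        if (spec$noise_acc_sd > 0)
          acc_sensor <- acc_sensor + matrix(stats::rnorm(3 * n, 0, spec$noise_acc_sd), n)
        gyro <- omega
        if (spec$noise_gyro_sd > 0)
          gyro <- gyro + matrix(stats::rnorm(3 * n, 0, spec$noise_gyro_sd), n)

        sensors[[key]] <- sensor_recording(loc, fs, acc_sensor, gyro, q)
        gt_acc[[key]] <- a_global
      }
      list(sensors = sensors,
           gt = list(peak_times = peak_times, a_global = gt_acc))
    })
    passages[[p]] <- res$sensors
    gt_passages[[p]] <- res$gt
  }

  session <- gait_session(horse_id, template$gait, run, passages)
  attr(session, "ground_truth") <- list(
    stride_freq = f0,
    passages = gt_passages
  )
  session
}

#' Generate a synthetic herd (paired before/after sessions per horse)
#'
#' Before-runs are always generated effect-free; `effect` applies to the
#' after-runs only, emulating a hypothesized training-session effect.
#'
#' @param spec a [herd_spec()]
#' @param template a [gait_template()]
#' @param effect a [fatigue_effect()] applied to after-runs
#' @return list with one element per horse:
#'   `list(horse_id, before = session, after = session)`
#' @export
generate_herd <- function(spec, template, effect = fatigue_effect()) {
  lapply(seq_len(spec$n_horses), function(h) {
    horse_id <- sprintf("H%02d", h)
    list(
      horse_id = horse_id,
      before = generate_session(template, fatigue_effect(), spec, horse_id,
                                "before", horse_index = h),
      after = generate_session(template, effect, spec, horse_id,
                               "after", horse_index = h)
    )
  })
}

#' Write a herd to a directory tree
#'
#' Layout: `dir/<horse_id>/<run>/` session containers, readable by
#' [read_session()] and consumable by [run_pipeline()] in directory mode.
#'
#' @param herd output of [generate_herd()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_herd <- function(herd, dir) {
  for (entry in herd) {
    write_session(entry$before, file.path(dir, entry$horse_id, "before"))
    write_session(entry$after, file.path(dir, entry$horse_id, "after"))
  }
  invisible(dir)
}

#' Read a herd directory tree written by [write_herd()]
#' @param dir directory
#' @return list as produced by [generate_herd()]
#' @export
read_herd <- function(dir) {
  horses <- sort(list.dirs(dir, recursive = FALSE))
  lapply(horses, function(hd) {
    list(
      horse_id = basename(hd),
      before = read_session(file.path(hd, "before")),
      after = read_session(file.path(hd, "after"))
    )
  })
}
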