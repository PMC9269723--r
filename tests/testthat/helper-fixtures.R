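# Small fixture builders; everything is generated in code at test time.

quick_spec <- function(seed = 1, n_horses = 2, sensors = c("ST", "FC_left"),
                       duration_s = 8, noise_acc_sd = 0.3, noise_gyro_sd = 0.05,
                       jitter_sd = 0.02, passages_per_run = 2, fs = 128) {
  herd_spec(n_horses = n_horses, passages_per_run = passages_per_run,
            duration_s = duration_s, fs = fs, noise_acc_sd = noise_acc_sd,
            noise_gyro_sd = noise_gyro_sd, jitter_sd = jitter_sd,
            seed = seed, sensors = sensors)
}

quick_session <- function(seed = 1, gait = "trot", run = "before",
                          effect = fatigue_effect(), ...) {
  generate_session(gait_template(gait), effect, quick_spec(seed, ...),
                   "H01", run, horse_index = 1)
}

# a static recording: constant attitude, gravity-only accelerometer reading
static_recording <- function(quat_row = c(1, 0, 0, 0), n = 300, fs = 128,
                             location = sensor_location("ST")) {
  q <- matrix(quat_row, n, 4, byrow = TRUE)
  g_sensor <- quat_rotate(quat_conjugate(matrix(quat_row, 1)), c(0, 0, 9.81))
  acc <- matrix(g_sensor, n, 3, byrow = TRUE)
  sensor_recording(location, fs, acc, matrix(0, n, 3), q)
}

# recording with prescribed quaternion trajectory and zero gyro/acc streams
quat_recording <- function(q, fs = 128, location = sensor_location("FC", "left")) {
  n <- nrow(q)
  g_sensor <- quat_rotate(quat_conjugate(q), matrix(c(0, 0, 9.81), 1))
  sensor_recording(location, fs, g_sensor, matrix(0, n, 3), q)
}

random_indicator_records <- function(n) {
  combos <- expand.grid(
    horse = sprintf("H%02d", 1:10), gait = c("trot", "canter"),
    sensor = c("ST", "SA", "FH"), channel = sprintf("ch%02d", 1:10),
    indicator = c("CC", "RMSD"), scope = c("intra_before", "inter"),
    stringsAsFactors = FALSE
  )
  combos <- combos[seq_len(n), ]
  data.frame(combos, side = "midline", run = NA_character_,
             value = stats::runif(n))
}
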