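test_that("a static sensor reads zero movement acceleration at any attitude", {
  # identity attitude
  rec <- static_recording(c(1, 0, 0, 0))
  g <- resolve_global_acceleration(rec)
  expect_lt(max(abs(g$acc_vert)), 1e-9)
  expect_lt(max(abs(g$acc_horiz)), 1e-9)
  a <- axis_vertical_angles(rec)
  expect_equal(a$angle_xv[1], 90)
  expect_equal(a$angle_yv[1], 90)
  expect_equal(a$angle_zv[1], 0)
  # -90 deg about y maps sensor x to +z: gravity is read on the x axis
  q <- quat_from_axis_angle(c(0, 1, 0), -pi / 2)
  rec2 <- static_recording(q)
  expect_equal(rec2$acc[1, ], c(9.81, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  g2 <- resolve_global_acceleration(rec2)
  expect_lt(max(abs(g2$acc_vert)), 1e-9)
  expect_lt(max(abs(g2$acc_horiz)), 1e-9)
  # +90 deg about y maps sensor x to -z: x axis points straight down
  rec3 <- static_recording(quat_from_axis_angle(c(0, 1, 0), pi / 2))
  expect_equal(axis_vertical_angles(rec3)$angle_xv[1], 180)
})

test_that("global resolution and axis angles match brute-force matrix oracles", {
  set.seed(41)
  n <- 300
  q <- random_unit_quats(n)
  acc <- matrix(rnorm(3 * n, sd = 5), n, 3)
  rec <- list(location = sensor_location("ST"), fs = 128, acc = acc,
              gyro = matrix(0, n, 3), quat = q)
  class(rec) <- "sensor_recording"
  g <- resolve_global_acceleration(rec)
  ang <- axis_vertical_angles(rec)
  for (i in seq_len(n)) {
    R <- rotmat_oracle(q[i, ])
    a_g <- R %*% acc[i, ] - c(0, 0, 9.81)
    expect_lt(abs(g$acc_vert[i] - a_g[3]), 1e-10)
    expect_lt(abs(g$acc_horiz[i] - sqrt(sum(a_g[1:2]^2))), 1e-10)
    expect_lt(abs(ang$angle_xv[i] - 180 / pi * acos(max(-1, min(1, R[3, 1])))), 1e-10)
    expect_lt(abs(ang$angle_zv[i] - 180 / pi * acos(max(-1, min(1, R[3, 3])))), 1e-10)
  }
})

test_that("horizontal acceleration is invariant under global yaw", {
  set.seed(42)
  n <- 200
  q <- random_unit_quats(n)
  acc <- matrix(rnorm(3 * n, sd = 5), n, 3)
  base <- list(location = sensor_location("ST"), fs = 128, acc = acc,
               gyro = matrix(0, n, 3), quat = q)
  class(base) <- "sensor_recording"
  yawed <- base
  yawed$quat <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), 1.2345), q)
  g1 <- resolve_global_acceleration(base)
  g2 <- resolve_global_acceleration(yawed)
  expect_lt(max(abs(g1$acc_horiz - g2$acc_horiz)), 1e-10)
  expect_lt(max(abs(g1$acc_vert - g2$acc_vert)), 1e-10)
})

test_that("swing-twist decomposes pure rotations correctly and recomposes", {
  n <- 260
  # identity relative rotation
  q_id <- matrix(c(1, 0, 0, 0), n, 4, byrow = TRUE)
  rec <- quat_recording(q_id)
  st <- swing_twist(rec, reference = c(1, 0, 0, 0))
  expect_lt(max(abs(st$swing)), 1e-9)
  expect_lt(max(abs(st$twist)), 1e-9)
  # pure twist of 30 degrees about the limb axis
  q_tw <- quat_from_axis_angle(c(1, 0, 0), rep(pi / 6, n))
  st <- swing_twist(quat_recording(q_tw), reference = c(1, 0, 0, 0))
  expect_equal(st$twist[1], 30, tolerance = 1e-9)
  expect_lt(max(abs(st$swing)), 1e-9)
  # random relative rotations: q_swing * q_twist recomposes q_rel,
  # q_twist is about the twist axis, q_swing orthogonal to it
  set.seed(43)
  q <- random_unit_quats(n)
  rec <- quat_recording(q)
  ref <- c(1, 0, 0, 0)
  st <- swing_twist(rec, reference = ref)
  q_rel <- quat_canonical(quat_multiply(quat_conjugate(matrix(ref, 1)), q))
  recomposed <- quat_multiply(st$q_swing, st$q_twist)
  for (i in seq_len(n)) {
    expect_lt(quat_distance(recomposed[i, ], q_rel[i, ]), 1e-10)
    expect_lt(abs(st$q_swing[i, 2]), 1e-10)  # swing axis orthogonal to x
  }
})

test_that("the degenerate 180-degree orthogonal rotation yields zero twist", {
  n <- 260
  q180 <- quat_from_axis_angle(c(0, 1, 0), rep(pi, n))  # 180 deg about y
  st <- swing_twist(quat_recording(quat_normalize(q180)), reference = c(1, 0, 0, 0))
  expect_true(all(st$degenerate))
  expect_equal(st$twist, rep(0, n))
  expect_equal(abs(st$swing), rep(180, n), tolerance = 1e-6)
})

test_that("channel sets serialize to one CSV column per channel", {
  s <- quick_session(seed = 62, sensors = "FC_left")
  cs <- derive_channels(s$passages[[1]]$FC_left)
  path <- withr::local_tempfile(fileext = ".csv")
  write_channel_set(cs, path)
  df <- utils::read.csv(path)
  expect_identical(names(df), c("t", names(cs$channels)))
  expect_equal(df$acc_vert, cs$channels$acc_vert, tolerance = 1e-9)
})

test_that("channel accounting is 13 for cannons and 11 otherwise", {
  s <- quick_session(seed = 6, sensors = c("ST", "FH", "SA", "FC_left", "HC_right"))
  pas <- s$passages[[1]]
  for (key in names(pas)) {
    cs <- derive_channels(pas[[key]])
    expected <- if (key %in% c("FC_left", "HC_right")) 13 else 11
    expect_length(cs$channels, expected)
  }
  # zero-motion recording: every movement channel is identically ~zero
  rec <- static_recording(quat_from_axis_angle(c(0, 1, 0), pi / 2),
                          location = sensor_location("FC", "left"))
  cs <- derive_channels(rec)
  expect_length(cs$channels, 13)
  for (ch in c("acc_vert", "acc_horiz", "gyro_x", "gyro_y", "gyro_z",
               "swing", "twist")) {
    expect_lt(max(abs(cs$channels[[ch]])), 1e-6)
  }
})
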