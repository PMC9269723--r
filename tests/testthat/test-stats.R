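test_that("paired Wilcoxon handles degenerate and textbook cases exactly", {
  x <- rnorm(10)
  res <- wilcoxon_paired(x, x)
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  # all-positive differences, n = 6: exact two-sided p = 2/64
  x <- rep(0, 6)
  y <- 1:6
  res <- wilcoxon_paired(x, y)
  expect_equal(res$p_value, 2 / 64)
  expect_equal(res$direction, "increase")
  expect_error(wilcoxon_paired(1:3, 4:6), "insufficient pairs")
})

test_that("exact p-values match brute-force enumeration and wilcox.test", {
  set.seed(81)
  for (i in 1:12) {
    n <- sample(6:11, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, mean = 0.4)
    res <- wilcoxon_paired(x, y)
    expect_lt(abs(res$p_value - wilcoxon_enum_oracle(x, y)), 1e-12)
    # tie-free continuous data: R's exact signed-rank test agrees
    ref <- stats::wilcox.test(y, x, paired = TRUE, exact = TRUE)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  }
  # ties among |differences| (average ranks): enumeration oracle still applies
  x <- c(0, 0, 0, 0, 0, 0, 0)
  y <- c(1, 1, -1, 2, 2, 3, 4)
  expect_lt(abs(wilcoxon_paired(x, y)$p_value - wilcoxon_enum_oracle(x, y)), 1e-12)
})

test_that("the test is symmetric under argument exchange", {
  set.seed(82)
  x <- rnorm(9); y <- rnorm(9, 0.5)
  a <- wilcoxon_paired(x, y)
  b <- wilcoxon_paired(y, x)
  expect_equal(a$p_value, b$p_value)
  expect_true((a$direction == "increase") == (b$direction == "decrease"))
})

test_that("large-sample normal approximation tracks wilcox.test", {
  set.seed(83)
  x <- rnorm(40); y <- x + rnorm(40, 0.3)
  res <- wilcoxon_paired(x, y)
  ref <- stats::wilcox.test(y, x, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

screen_fixture <- function() {
  set.seed(84)
  horses <- sprintf("H%02d", 1:10)
  make <- function(channel, indicator, scope, value) {
    data.frame(horse = horses, gait = "trot", sensor = "ST", side = "midline",
               channel = channel, indicator = indicator, scope = scope,
               run = NA_character_, value = value)
  }
  rbind(
    # clear effect, high pre-training repeatability: retained
    make("acc_vert", "CC", "intra_before", 0.92 + rnorm(10, 0, 0.01)),
    make("acc_vert", "CC", "inter", 0.80 + rnorm(10, 0, 0.01)),
    # clear effect but poor pre-training repeatability: screened out
    make("gyro_x", "CC", "intra_before", 0.70 + rnorm(10, 0, 0.01)),
    make("gyro_x", "CC", "inter", 0.55 + rnorm(10, 0, 0.01)),
    # RMSD effect: retained regardless of any CC level
    make("acc_vert", "RMSD", "intra_before", 2.0 + rnorm(10, 0, 0.1)),
    make("acc_vert", "RMSD", "inter", 3.0 + rnorm(10, 0, 0.1)),
    # null indicator
    make("acc_x", "CC", "intra_before", 0.90 + rnorm(10, 0, 0.02)),
    make("acc_x", "CC", "inter", 0.90 + rnorm(10, 0, 0.02))
  )
}

test_that("screening pairs the right scopes and applies the CC retention rule", {
  res <- screen_indicators(screen_fixture())
  res <- apply_cc_retention(res)
  row <- function(ch, ind) res[res$channel == ch & res$indicator == ind, ]
  strong <- row("acc_vert", "CC")
  expect_true(strong$significant)
  expect_true(strong$retained)
  expect_equal(strong$direction, "decrease")
  expect_equal(strong$n_pairs, 10)
  low_cc <- row("gyro_x", "CC")
  expect_true(low_cc$significant)
  expect_false(low_cc$retained)  # mean intra-before CC 0.70 < 0.80
  rmsd <- row("acc_vert", "RMSD")
  expect_true(rmsd$significant)
  expect_true(rmsd$retained)
  null_row <- row("acc_x", "CC")
  expect_false(null_row$significant)
  # retention never adds keys beyond the significant set
  expect_true(all(!res$retained[!res$significant]))
  expect_true(all(res$band[res$p_value < 0.01] == "p<0.01"))
})

test_that("the BH option adds adjusted p-values without changing raw ones", {
  res0 <- screen_indicators(screen_fixture())
  res1 <- screen_indicators(screen_fixture(), bh = TRUE)
  expect_false("p_bh" %in% names(res0))
  expect_equal(res1$p_bh, stats::p.adjust(res1$p_value, "BH"))
  expect_equal(res1$p_value, res0$p_value)
})

test_that("report tables format like the published tables and count per sensor", {
  res <- apply_cc_retention(screen_indicators(screen_fixture()))
  tab <- report_tables(res)
  expect_true(all(grepl("^-?\\d+\\.\\d{2} \\(\\d+\\.\\d{2}\\)$", tab$cc$group1)))
  expect_equal(fmt_mean_sd <- tab$cc$group1[tab$cc$channel == "acc_vert"],
               sprintf("%.2f (%.2f)",
                       res$mean_x[res$channel == "acc_vert" & res$indicator == "CC"],
                       res$sd_x[res$channel == "acc_vert" & res$indicator == "CC"]))
  # only retained CC keys appear in the CC table
  expect_false("gyro_x" %in% tab$cc$channel)
  counts <- tab$sensor_counts
  expect_equal(counts$n_significant[counts$sensor == "ST"],
               sum(res$significant))
  # an all-null screen yields empty tables and zero counts
  null_rec <- screen_fixture()
  null_rec <- null_rec[null_rec$channel == "acc_x", ]
  res0 <- apply_cc_retention(screen_indicators(null_rec))
  tab0 <- report_tables(res0)
  expect_equal(nrow(tab0$cc), 0)
  expect_equal(nrow(tab0$rmsd), 0)
  expect_true(all(tab0$sensor_counts$n_significant == 0))
})

test_that("cannon sides are pooled per horse before testing", {
  set.seed(85)
  horses <- sprintf("H%02d", 1:8)
  rec <- do.call(rbind, lapply(c("left", "right"), function(sd) {
    offset <- if (sd == "left") 0.05 else -0.05
    rbind(
      data.frame(horse = horses, gait = "trot", sensor = "FC", side = sd,
                 channel = "swing", indicator = "CC", scope = "intra_before",
                 run = NA_character_, value = 0.9 + offset + rnorm(8, 0, 0.01)),
      data.frame(horse = horses, gait = "trot", sensor = "FC", side = sd,
                 channel = "swing", indicator = "CC", scope = "inter",
                 run = NA_character_, value = 0.8 + offset + rnorm(8, 0, 0.01))
    )
  }))
  pooled <- screen_indicators(rec)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$sensor, "FC")
  split_res <- screen_indicators(rec, pool_cannon_sides = FALSE)
  expect_equal(nrow(split_res), 2)
  expect_setequal(split_res$sensor, c("FC_left", "FC_right"))
})
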