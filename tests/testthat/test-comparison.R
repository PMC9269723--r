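test_that("stride normalization reproduces constants, lines and endpoints", {
  expect_equal(normalize_stride(rep(2.5, 17)), rep(2.5, 100))
  ramp <- seq(-3, 8, length.out = 23)
  out <- normalize_stride(ramp)
  expect_equal(out, seq(-3, 8, length.out = 100), tolerance = 1e-12)
  set.seed(51)
  y <- cumsum(rnorm(37))
  out <- normalize_stride(y)
  expect_length(out, 100)
  expect_identical(out[1], y[1])
  expect_identical(out[100], y[37])
  expect_error(normalize_stride(1:3), "too short")
})

test_that("stride normalization matches an independent PCHIP oracle", {
  set.seed(52)
  for (len in c(17, 37, 91)) {
    y <- cumsum(rnorm(len)) + sin(seq(0, 3, length.out = len))
    xi <- seq(0, 1, length.out = len)
    xo <- seq(0, 1, length.out = 100)
    expect_lt(max(abs(normalize_stride(y) - pchip_oracle(xi, y, xo))), 1e-10)
  }
})

test_that("the reference stride minimizes RMSD to the mean", {
  # identical strides: tie broken to the first row
  g <- build_stride_group(matrix(1:100, 3, 100, byrow = TRUE))
  expect_equal(g$ref_index, 1)
  # an outlier never becomes the reference
  base <- matrix(rep(sin(seq(0, 2 * pi, length.out = 100)), 4), 4, byrow = TRUE)
  g <- build_stride_group(rbind(base, 10 + 5 * cos(seq(0, 2 * pi, length.out = 100))))
  expect_lte(g$ref_index, 4)
  # random groups: match exhaustive enumeration, and the defining property
  set.seed(53)
  for (rep_i in 1:20) {
    m <- matrix(rnorm(800), 8, 100)
    g <- build_stride_group(m)
    mean_s <- colMeans(m)
    rmsd_all <- apply(m, 1, function(r) sqrt(mean((r - mean_s)^2)))
    expect_equal(g$ref_index, which.min(rmsd_all))
    expect_true(all(g$rmsd_to_mean[g$ref_index] <= g$rmsd_to_mean + 1e-12))
  }
  expect_error(build_stride_group(matrix(1, 1, 100)), "at least 2")
})

test_that("stride comparison behaves like Pearson CC and RMSD should", {
  s <- sin(seq(0, 2 * pi, length.out = 100))
  expect_equal(compare_strides(s, s), list(cc = 1, rmsd = 0, degenerate = FALSE))
  off <- compare_strides(s, s + 2)
  expect_equal(off$cc, 1)
  expect_equal(off$rmsd, 2)
  anti <- compare_strides(s, -s)  # s is zero-mean
  expect_equal(anti$cc, -1)
  expect_equal(anti$rmsd, 2 * sqrt(mean(s^2)), tolerance = 1e-12)
  # symmetry and scale behavior
  set.seed(54)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(compare_strides(a, b), compare_strides(b, a))
  sc <- compare_strides(3 * a, 3 * b)
  expect_equal(sc$cc, compare_strides(a, b)$cc, tolerance = 1e-12)
  expect_equal(sc$rmsd, 3 * compare_strides(a, b)$rmsd, tolerance = 1e-12)
  # zero-variance input: CC flagged missing, RMSD still computed
  z <- compare_strides(rep(1, 100), b)
  expect_true(z$degenerate)
  expect_true(is.na(z$cc))
  expect_false(is.na(z$rmsd))
})

test_that("run indicators respond correctly to null, offset and shape effects", {
  set.seed(55)
  template <- sin(seq(0, 2 * pi, length.out = 100))
  strides <- t(replicate(8, template + rnorm(100, sd = 0.1)))
  gb <- build_stride_group(strides)
  # identical groups: intra equals the restricted inter comparisons; the full
  # inter mean additionally contains the reference's exact self-match
  ri <- run_indicators(gb, gb)
  v <- function(ind, scope) ri$value[ri$indicator == ind & ri$scope == scope]
  expect_gte(v("CC", "inter"), v("CC", "intra_before"))
  expect_lte(v("RMSD", "inter"), v("RMSD", "intra_before"))
  expect_equal(v("CC", "intra_before"), v("CC", "intra_after"))
  # constant offset: correlations untouched, RMSD strictly larger
  ga <- build_stride_group(strides + 2)
  ri <- run_indicators(gb, ga)
  expect_equal(v("CC", "intra_before"), v("CC", "intra_after"), tolerance = 1e-12)
  expect_gt(v("RMSD", "inter"), v("RMSD", "intra_before"))
  expect_gt(v("RMSD", "inter"), 1.9)  # dominated by the offset of 2
})

test_that("indicator records cover all channels, scopes and runs", {
  spec <- quick_spec(seed = 61, n_horses = 2, sensors = c("ST", "HC_left"))
  herd <- generate_herd(spec, gait_template("trot"), fatigue_effect())
  rec <- herd_indicators(herd)
  expect_setequal(unique(rec$indicator),
                  c("CC", "RMSD", "SPARC", "LDLJ", "stride_duration"))
  cc <- rec[rec$indicator == "CC" & rec$horse == "H01", ]
  expect_setequal(unique(cc$scope),
                  c("intra_before", "intra_after", "inter", "inter_rev"))
  # 11 channels for the sternum, 13 for the cannon
  expect_length(unique(cc$channel[cc$sensor == "ST"]), 11)
  expect_length(unique(cc$channel[cc$sensor == "HC"]), 13)
  # SPARC additionally covers the angular velocity norm
  sp <- rec[rec$indicator == "SPARC" & rec$horse == "H01" & rec$sensor == "ST", ]
  expect_length(unique(sp$channel), 12)
  expect_true(all(rec$value[rec$indicator == "SPARC"] <= -1))
  expect_true(all(rec$value[rec$indicator == "stride_duration"] > 0))
  # CC values are proper correlations
  expect_true(all(abs(rec$value[rec$indicator == "CC"]) <= 1))
})
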