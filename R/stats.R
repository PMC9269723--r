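# Paired Wilcoxon screening ---------------------------------------------------

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired samples. Pairs with missing values
#' are removed; zero differences are dropped (Wilcoxon's original treatment)
#' and ties among absolute differences receive average ranks. For n <= 15
#' (after dropping) the p-value is exact, by full enumeration of the 2^n sign
#' assignments of the statistic `W` (sum of ranks of positive differences,
#' two-sided via the symmetry of `W` about its null mean); above that a
#' normal approximation with continuity correction is used.
#'
#' @param x,y paired numeric vectors of equal length
#' @param exact_max_n largest n for which the exact enumeration is used
#' @return list with `p_value`, `statistic` (W), `n` (pairs used),
#'   `direction` (`"increase"`/`"decrease"`/`"none"`, the sign of the median
#'   of `y - x`), and `degenerate` (TRUE when all differences are zero, in
#'   which case `p_value = 1`)
#' @export
wilcoxon_paired <- function(x, y, exact_max_n = 15) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 5) stop("insufficient pairs (need >= 5 complete pairs)")
  d <- y - x
  med <- stats::median(d)
  direction <- if (med > 0) "increase" else if (med < 0) "decrease" else "none"
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p_value = 1, statistic = NA_real_, n = 0,
                direction = "none", degenerate = TRUE))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- sum(r) / 2
  if (n <= exact_max_n) {
    # all 2^n sign assignments; distribution of W is symmetric about mu
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    W_all <- as.numeric(signs %*% r)
    p <- mean(abs(W_all - mu) >= abs(W - mu) - 1e-9)
  } else {
    sigma <- sqrt(sum(r^2)) / 2
    z <- (abs(W - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-z))
  }
  list(p_value = p, statistic = W, n = n, direction = direction,
       degenerate = FALSE)
}

significance_band <- function(p) {
  ifelse(p < 0.01, "p<0.01", ifelse(p < 0.05, "0.01<=p<0.05", "ns"))
}

# scopes compared per indicator family
scope_pair_for <- function(indicator) {
  if (indicator %in% c("CC", "RMSD")) c("intra_before", "inter")
  else c("before", "after")
}

#' Screen all indicators for a training-session effect
#'
#' For each (gait, sensor, channel, indicator) key the per-horse paired
#' values of the two relevant scopes are compared with a paired Wilcoxon
#' test: CC and RMSD compare `intra_before` (null condition) against `inter`
#' (training-effect condition); SPARC, LDLJ and stride duration compare the
#' `before` against the `after` run. Left/right cannon sensors are pooled by
#' averaging per horse before testing (configurable). No multiple-testing
#' correction is applied by default; a Benjamini-Hochberg adjusted p-value
#' column can be added.
#'
#' @param records indicator record data.frame (see [write_indicator_table()])
#' @param alpha significance level (default 0.05)
#' @param pool_cannon_sides average left/right cannon values per horse
#'   (default TRUE)
#' @param bh also compute Benjamini-Hochberg adjusted p-values (default FALSE)
#' @return data.frame of screen results: one row per key with `n_pairs`,
#'   `p_value`, `direction`, group means/SDs, significance `band`,
#'   `significant`, and `retained` (initialized to `significant`; see
#'   [apply_cc_retention()])
#' @export
screen_indicators <- function(records, alpha = 0.05, pool_cannon_sides = TRUE,
                              bh = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  rec <- records
  if (pool_cannon_sides) {
    agg <- stats::aggregate(
      value ~ horse + gait + sensor + channel + indicator + scope,
      data = rec, FUN = mean)
  } else {
    rec$sensor <- ifelse(rec$side %in% c("left", "right"),
                         paste(rec$sensor, rec$side, sep = "_"), rec$sensor)
    agg <- stats::aggregate(
      value ~ horse + gait + sensor + channel + indicator + scope,
      data = rec, FUN = mean)
  }

  keys <- unique(agg[, c("gait", "sensor", "channel", "indicator")])
  rows <- list()
  for (k in seq_len(nrow(keys))) {
    key <- keys[k, ]
    sub <- merge(agg, key)
    scopes <- scope_pair_for(key$indicator)
    xs <- sub[sub$scope == scopes[1], c("horse", "value")]
    ys <- sub[sub$scope == scopes[2], c("horse", "value")]
    m <- merge(xs, ys, by = "horse", suffixes = c("_x", "_y"))
    if (nrow(m) < 5 || !all(scopes %in% sub$scope)) {
      warning("key skipped (missing scope or too few pairs): ",
              paste(unlist(key), collapse = "/"))
      next
    }
    wt <- wilcoxon_paired(m$value_x, m$value_y)
    rows[[length(rows) + 1]] <- data.frame(
      gait = key$gait, sensor = key$sensor, channel = key$channel,
      indicator = key$indicator,
      scope_x = scopes[1], scope_y = scopes[2],
      n_pairs = nrow(m), p_value = wt$p_value, direction = wt$direction,
      mean_x = mean(m$value_x), sd_x = stats::sd(m$value_x),
      mean_y = mean(m$value_y), sd_y = stats::sd(m$value_y)
    )
  }
  if (!length(rows)) stop("no screenable indicator keys found")
  res <- do.call(rbind, rows)
  res$band <- significance_band(res$p_value)
  res$significant <- res$p_value < alpha
  if (bh) res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res$retained <- res$significant
  res[order(res$p_value), ]
}

#' Apply the CC retention rule
#'
#' CC indicators are retained only when, in addition to significance, the
#' mean across horses of the pre-training intra-run CC exceeds `threshold`
#' (channels that do not repeat well even before training are uninformative).
#' Other indicator families are retained iff significant; the rule never adds
#' keys beyond the significant set.
#'
#' @param results screen results from [screen_indicators()]
#' @param threshold minimum mean pre-training intra-run CC (default 0.80)
#' @return `results` with the `retained` column updated
#' @export
apply_cc_retention <- function(results, threshold = 0.80) {
  is_cc <- results$indicator == "CC"
  results$retained <- results$significant
  results$retained[is_cc] <- results$significant[is_cc] &
    results$mean_x[is_cc] > threshold
  results
}

fmt_mean_sd <- function(m, s) sprintf("%.2f (%.2f)", m, s)

#' Ranked report tables of screened indicators
#'
#' Produces per-indicator-family tables (CC, SPARC, RMSD) of the retained
#' indicators, formatted as `variable / axis / position / p / mean (SD)` per
#' compared scope, plus a per-sensor-location count of significant indicators
#' per gait.
#'
#' @param results screen results (after [apply_cc_retention()])
#' @return list with data.frames `cc`, `sparc`, `rmsd`, `ldlj`,
#'   `sensor_counts`
#' @export
report_tables <- function(results) {
  one_table <- function(ind, use_retained = TRUE) {
    sel <- results[results$indicator == ind &
                     (if (use_retained) results$retained else results$significant), ,
                   drop = FALSE]
    if (!nrow(sel)) {
      return(data.frame(gait = character(), channel = character(),
                        sensor = character(), p_value = numeric(),
                        group1 = character(), group2 = character()))
    }
    sel <- sel[order(sel$gait, sel$p_value), ]
    data.frame(
      gait = sel$gait, channel = sel$channel, sensor = sel$sensor,
      p_value = round(sel$p_value, 3),
      group1 = fmt_mean_sd(sel$mean_x, sel$sd_x),
      group2 = fmt_mean_sd(sel$mean_y, sel$sd_y)
    )
  }
  sig <- results[results$significant, , drop = FALSE]
  counts <- as.data.frame(table(sensor = sig$sensor, gait = sig$gait),
                          responseName = "n_significant")
  all_counts <- as.data.frame(table(sensor = results$sensor, gait = results$gait),
                              responseName = "n_total")
  counts <- merge(all_counts, counts, all.x = TRUE)
  counts$n_significant[is.na(counts$n_significant)] <- 0
  list(
    cc = one_table("CC"),
    sparc = one_table("SPARC"),
    rmsd = one_table("RMSD"),
    ldlj = one_table("LDLJ"),
    sensor_counts = counts[order(counts$gait, -counts$n_significant), ]
  )
}
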