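# Stride time-normalization and comparison -----------------------------------

#' Time-normalize a stride to a fixed number of points
#'
#' Shape-preserving piecewise-cubic Hermite (PCHIP) interpolation onto
#' `n_points` equally spaced points over \[0, 100\]% of the stride; the
#' endpoints are reproduced exactly and linear data are reproduced exactly.
#'
#' @param y numeric stride samples (length >= 4)
#' @param n_points number of output samples (default 100)
#' @return numeric vector of length `n_points`
#' @export
normalize_stride <- function(y, n_points = 100) {
  n <- length(y)
  if (n < 4) stop("stride too short to normalize (", n, " samples)")
  xi <- seq(0, 1, length.out = n)
  xo <- seq(0, 1, length.out = n_points)
  if (stats::sd(y) == 0) return(rep(y[1], n_points))
  pracma::pchip(xi, y, xo)
}

#' Group normalized strides and select the reference stride
#'
#' The reference stride of a group is the one minimizing the RMSD to the
#' pointwise mean stride (ties broken by the lowest row index).
#'
#' @param strides N x P matrix, one normalized stride per row (N >= 2)
#' @return an object of class `stride_group`: list with `strides`,
#'   `mean_stride`, `ref_index`, `rmsd_to_mean`
#' @export
build_stride_group <- function(strides) {
  strides <- as.matrix(strides)
  if (nrow(strides) < 2) stop("a stride group needs at least 2 strides")
  mean_stride <- colMeans(strides)
  rmsd <- sqrt(rowMeans(sweep(strides, 2, mean_stride)^2))
  structure(
    list(strides = strides, mean_stride = mean_stride,
         ref_index = which.min(rmsd), rmsd_to_mean = rmsd),
    class = "stride_group"
  )
}

#' Compare two normalized strides
#'
#' @param a,b numeric vectors of equal length
#' @return list with `cc` (Pearson correlation; `NA` with a `degenerate`
#'   flag when either input has zero variance) and `rmsd`
#'   (root-mean-square pointwise difference, in channel units)
#' @export
compare_strides <- function(a, b) {
  if (length(a) != length(b)) stop("strides must have equal length")
  rmsd <- sqrt(mean((a - b)^2))
  degenerate <- stats::sd(a) == 0 || stats::sd(b) == 0
  cc <- if (degenerate) NA_real_ else stats::cor(a, b)
  list(cc = cc, rmsd = rmsd, degenerate = degenerate)
}

# mean CC/RMSD of each row of `strides` against `reference`, optionally
# excluding one row (the reference itself in intra comparisons)
group_vs_reference <- function(strides, reference, exclude = 0) {
  rows <- setdiff(seq_len(nrow(strides)), exclude)
  cc <- numeric(0); rmsd <- numeric(0)
  for (i in rows) {
    cmp <- compare_strides(strides[i, ], reference)
    cc <- c(cc, cmp$cc); rmsd <- c(rmsd, cmp$rmsd)
  }
  list(cc = mean(cc, na.rm = TRUE), rmsd = mean(rmsd))
}

#' Intra- and inter-run similarity indicators for one channel
#'
#' Computes, for a before-run and an after-run group of normalized strides of
#' the same (horse, gait, sensor, channel):
#' * `intra_before` / `intra_after`: mean CC and RMSD of each stride against
#'   its own run's reference;
#' * `inter`: mean CC and RMSD of each after-stride against the
#'   before-run reference (the default screening direction);
#' * `inter_rev`: the symmetric direction (before-strides vs the after
#'   reference), stored but not used in the default screen.
#'
#' Intra comparisons exclude the reference stride compared against itself
#' (which would inject exact CC = 1 / RMSD = 0 values); inter comparisons use
#' every stride of the probing run, mirroring the comparison of each stride
#' to the other run's reference.
#'
#' @param before,after `stride_group` objects
#' @return data.frame with columns `indicator` (`CC`/`RMSD`), `scope`, `value`
#' @export
run_indicators <- function(before, after) {
  if (!inherits(before, "stride_group") || !inherits(after, "stride_group"))
    stop("before/after must be stride_group objects")
  ref_b <- before$strides[before$ref_index, ]
  ref_a <- after$strides[after$ref_index, ]
  res <- list(
    intra_before = group_vs_reference(before$strides, ref_b, exclude = before$ref_index),
    intra_after = group_vs_reference(after$strides, ref_a, exclude = after$ref_index),
    inter = group_vs_reference(after$strides, ref_b),
    inter_rev = group_vs_reference(before$strides, ref_a)
  )
  data.frame(
    indicator = rep(c("CC", "RMSD"), each = length(res)),
    scope = rep(names(res), times = 2),
    value = c(vapply(res, `[[`, numeric(1), "cc"),
              vapply(res, `[[`, numeric(1), "rmsd"))
  )
}
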