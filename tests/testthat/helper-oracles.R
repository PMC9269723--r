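# Independent oracle implementations used to cross-check the package.
# These deliberately use different algorithms/code paths than the package.

# rotation matrix from a unit quaternion via Rodrigues' axis-angle formula
rotmat_oracle <- function(q) {
  w <- q[1]; v <- q[2:4]
  s <- sqrt(sum(v^2))
  if (s < 1e-15) return(diag(3))
  axis <- v / s
  theta <- 2 * atan2(s, w)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_unit_quats <- function(n) {
  m <- matrix(stats::rnorm(4 * n), n, 4)
  m / sqrt(rowSums(m^2))
}

# angular distance between two unit quaternions, up to the q/-q double cover
quat_distance <- function(a, b) {
  min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))
}

# shape-preserving cubic Hermite interpolation, independently coded from the
# classic shape-preserving slope construction (weighted harmonic means in the
# interior, clipped non-centered one-sided differences at the ends)
pchip_oracle <- function(x, y, xq) {
  n <- length(x)
  h <- diff(x)
  delta <- diff(y) / h
  d <- numeric(n)
  for (k in 2:(n - 1)) {
    if (delta[k - 1] * delta[k] <= 0) {
      d[k] <- 0
    } else {
      w1 <- 2 * h[k] + h[k - 1]
      w2 <- h[k] + 2 * h[k - 1]
      d[k] <- (w1 + w2) / (w1 / delta[k - 1] + w2 / delta[k])
    }
  }
  endslope <- function(h1, h2, d1, d2) {
    s <- ((2 * h1 + h2) * d1 - h1 * d2) / (h1 + h2)
    if (sign(s) != sign(d1)) s <- 0
    else if (sign(d1) != sign(d2) && abs(s) > abs(3 * d1)) s <- 3 * d1
    s
  }
  d[1] <- endslope(h[1], h[2], delta[1], delta[2])
  d[n] <- endslope(h[n - 1], h[n - 2], delta[n - 1], delta[n - 2])
  out <- numeric(length(xq))
  for (i in seq_along(xq)) {
    k <- findInterval(xq[i], x, rightmost.closed = TRUE)
    k <- min(max(k, 1), n - 1)
    t <- (xq[i] - x[k]) / h[k]
    h00 <- (1 + 2 * t) * (1 - t)^2
    h10 <- t * (1 - t)^2
    h01 <- t^2 * (3 - 2 * t)
    h11 <- t^2 * (t - 1)
    out[i] <- h00 * y[k] + h10 * h[k] * d[k] + h01 * y[k + 1] + h11 * h[k] * d[k + 1]
  }
  out
}

# arc length of the normalized spectrum over [0, fc] by numerical quadrature
# on a `refine`-times finer frequency subdivision (linear interpolation)
sparc_arc_oracle <- function(v, fs, fc = 10, pad_factor = 4, refine = 10) {
  nfft <- 2^ceiling(log2(pad_factor * length(v)))
  mag <- Mod(stats::fft(c(v, numeric(nfft - length(v)))))
  half <- nfft %/% 2 + 1
  mag <- mag[seq_len(half)]
  freqs <- (seq_len(half) - 1) * fs / nfft
  vhat <- mag / max(mag)
  # refine each bin interval `refine`-fold; the spectrum polyline's own knots
  # must be grid points or the quadrature cuts its corners
  fine <- sort(unique(c(freqs[freqs <= fc], fc,
                        seq(0, fc, length.out = refine * sum(freqs <= fc) + 1))))
  vfine <- stats::approx(freqs, vhat, xout = fine)$y
  arc <- 0
  for (i in seq_len(length(fine) - 1)) {
    arc <- arc + sqrt(((fine[i + 1] - fine[i]) / fc)^2 + (vfine[i + 1] - vfine[i])^2)
  }
  -arc
}

# brute-force two-sided signed-rank p-value by explicit enumeration of all
# 2^n sign assignments (bit loop, independent of the package's matrix path)
wilcoxon_enum_oracle <- function(x, y) {
  d <- (y - x)
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  mu <- sum(r) / 2
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    W <- 0
    for (bit in seq_len(n)) {
      if (bitwAnd(mask, bitwShiftL(1L, bit - 1L)) != 0L) W <- W + r[bit]
    }
    if (abs(W - mu) >= abs(W_obs - mu) - 1e-9) count <- count + 1L
  }
  count / 2^n
}
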