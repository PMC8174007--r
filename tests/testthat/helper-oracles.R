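# Independent oracles used across the suite. These deliberately use naive
# direct computation (double loops, exhaustive enumeration, closed forms)
# and share no code with the package internals they check.

# MSD by the literal double-loop definition.
msd_oracle <- function(x, y, dt, n_max) {
  n <- length(x)
  vapply(seq_len(n_max), function(lag) {
    s <- 0
    for (i in seq_len(n - lag)) {
      s <- s + (x[i + lag] - x[i])^2 + (y[i + lag] - y[i])^2
    }
    s / (n - lag)
  }, numeric(1))
}

# Minimum total cost over every link/birth/death combination for two
# frames of points, by exhaustive recursion. Links farther than max_dist
# are not allowed; each unlinked source is a death and each unlinked
# target a birth, both at cost alt.
lap_enumeration_oracle <- function(xy_t, xy_next, max_dist, alt) {
  n <- nrow(xy_t)
  m <- nrow(xy_next)
  d2 <- matrix(Inf, max(n, 1), max(m, 1))
  if (n > 0 && m > 0) {
    for (i in seq_len(n)) {
      for (j in seq_len(m)) {
        v <- (xy_t[i, 1] - xy_next[j, 1])^2 + (xy_t[i, 2] - xy_next[j, 2])^2
        if (v <= max_dist^2) d2[i, j] <- v
      }
    }
  }
  best <- Inf
  recurse <- function(i, used, cost) {
    if (cost >= best) {
      return()
    }
    if (i > n) {
      total <- cost + alt * (m - sum(used))
      if (total < best) best <<- total
      return()
    }
    recurse(i + 1, used, cost + alt) # death of i
    if (m > 0) {
      for (j in seq_len(m)) {
        if (!used[j] && is.finite(d2[i, j])) {
          used[j] <- TRUE
          recurse(i + 1, used, cost + d2[i, j])
          used[j] <- FALSE
        }
      }
    }
  }
  recurse(1, rep(FALSE, m), 0)
  best
}

# Closed-form simple linear regression (normal equations).
ols_oracle <- function(x, y) {
  sx <- sum(x)
  sy <- sum(y)
  n <- length(x)
  slope <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# Exact Wilcoxon signed-rank p (two-sided) by enumerating all 2^n sign
# assignments of |differences| (no ties, no zeros).
wilcoxon_exact_oracle <- function(diffs) {
  n <- length(diffs)
  r <- rank(abs(diffs))
  v_obs <- sum(r[diffs > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}

# KS D statistic as the maximum ECDF gap evaluated on the pooled sample.
ks_d_oracle <- function(a, b) {
  pts <- sort(c(a, b))
  max(abs(vapply(
    pts,
    function(t) mean(a <= t) - mean(b <= t),
    numeric(1)
  )))
}

# Dense direct convolution of an image with a kernel, replicate borders
# (quadruple loop; small images only).
dense_conv_oracle <- function(img, k) {
  r <- (nrow(k) - 1) %/% 2
  h <- nrow(img)
  w <- ncol(img)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (a in -r:r) {
        for (b in -r:r) {
          ii <- min(max(i + a, 1), h)
          jj <- min(max(j + b, 1), w)
          acc <- acc + img[ii, jj] * k[a + r + 1, b + r + 1]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Render one symmetric Gaussian spot on a flat background by the pixel
# centre formula; independent fixture for detection tests. x0/y0 are
# 0-based pixel coordinates.
spot_frame <- function(h, w, x0, y0, amp, sigma, bg = 0) {
  xg <- matrix(rep(0:(w - 1), each = h), h, w)
  yg <- matrix(rep(0:(h - 1), times = w), h, w)
  f <- bg
  for (k in seq_along(x0)) {
    f <- f + amp[min(k, length(amp))] *
      exp(-((xg - x0[k])^2 + (yg - y0[k])^2) /
        (2 * sigma[min(k, length(sigma))]^2))
  }
  f
}
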