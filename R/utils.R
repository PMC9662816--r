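# Internal numeric helpers shared across modules.

# Smallest 5-smooth integer >= n.  Used to pick FFT-friendly padded lengths;
# R's mixed-radix FFT degrades badly on large prime factors.
next_smooth <- function(n) {
  stopifnot(n >= 1)
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

# Lagged cross-correlation counts between two sorted integer position vectors.
# Returns counts of pairs (a, b) with b - a = tau for tau in -max_lag..max_lag.
# Positions from different trials must be offset by > max_lag so that
# cross-trial products never form.
sparse_xcorr_counts <- function(pos_a, pos_b, max_lag) {
  n_lags <- 2L * max_lag + 1L
  if (length(pos_a) == 0L || length(pos_b) == 0L) return(integer(n_lags))
  lo <- findInterval(pos_a - max_lag - 1L, pos_b)
  hi <- findInterval(pos_a + max_lag, pos_b)
  counts <- hi - lo
  keep <- counts > 0L
  if (!any(keep)) return(integer(n_lags))
  idx <- sequence(counts[keep], from = lo[keep] + 1L)
  diffs <- pos_b[idx] - rep(pos_a[keep], counts[keep])
  tabulate(diffs + max_lag + 1L, nbins = n_lags)
}

# Cross-correlation of two equal-length real vectors via FFT:
# out[tau] = sum_t a[t] * b[t + tau], tau in -max_lag..max_lag, circularly;
# callers must zero-pad so circular wrap never mixes trials.
fft_xcorr <- function(fa, fb, len, max_lag) {
  cc <- Re(fft(Conj(fa) * fb, inverse = TRUE)) / len
  # lag 0 at index 1, positive lags 2..max_lag+1, negative from the tail
  c(cc[(len - max_lag + 1L):len], cc[1L:(max_lag + 1L)])
}

# Gaussian kernel smoothing along a uniformly spaced axis with reflected
# boundaries.  sigma in the same units as spacing.
gaussian_smooth <- function(y, spacing, sigma) {
  if (sigma <= 0) return(y)
  n <- length(y)
  half <- max(1L, ceiling(4 * sigma / spacing))
  kern <- exp(-0.5 * ((-half:half) * spacing / sigma)^2)
  kern <- kern / sum(kern)
  pad <- c(y[pmin(half:1, n)], y, y[pmax(n - (1:half) + 1L, 1L)])
  as.numeric(stats::filter(pad, kern, sides = 2))[(half + 1L):(half + n)]
}

# Two-sided one-proportion z-test against p0 (normal approximation).
one_proportion_z_test <- function(successes, n, p0 = 0.5) {
  stopifnot(n > 0, p0 > 0, p0 < 1)
  phat <- successes / n
  z <- (phat - p0) / sqrt(p0 * (1 - p0) / n)
  list(estimate = phat, z = z, p_value = 2 * pnorm(-abs(z)), n = n)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 for identical partitions (up to label permutation), ~0 at chance.
#' Used to score recovery of planted cluster structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return Numeric scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Full width of a curve at half height around its maximum, in x-axis units.
# Height measured from `baseline` (default 0) to the peak; width is the span
# of the contiguous run of samples >= half height containing the peak, with
# linear interpolation at the edges.
half_height_width <- function(x, y, baseline = 0) {
  i <- which.max(y)
  thr <- baseline + (y[i] - baseline) / 2
  if (!is.finite(thr) || y[i] <= baseline) return(NA_real_)
  lo <- i
  while (lo > 1L && y[lo - 1L] >= thr) lo <- lo - 1L
  hi <- i
  n <- length(y)
  while (hi < n && y[hi + 1L] >= thr) hi <- hi + 1L
  left <- if (lo > 1L) {
    x[lo] - (x[lo] - x[lo - 1L]) * (y[lo] - thr) / (y[lo] - y[lo - 1L])
  } else x[1L]
  right <- if (hi < n) {
    x[hi] + (x[hi + 1L] - x[hi]) * (y[hi] - thr) / (y[hi] - y[hi + 1L])
  } else x[n]
  right - left
}

# Derive a reproducible child seed (< 2^31) from a base seed and a tag.
child_seed <- function(seed, tag) {
  (as.integer(seed) + sum(utf8ToInt(tag)) * 1009L) %% 2147483563L
}
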