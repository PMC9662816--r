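# Core CCG machinery: raw, jitter-expected, and corrected cross-correlograms,
# peak/trough significance, double-count screening, and the all-pairs driver.
#
# The CCG between reference j and target k is
#   CCG_{j-k}(tau) = (1/M) sum_i sum_t x_ji(t) x_ki(t+tau)
#                    / ( theta(tau) sqrt(lambda_j lambda_k) )
# with theta(tau) = N - |tau| correcting for overlap and lambda in spikes per
# bin, so the CCG is dimensionless (coincidences per spike).  Positive tau
# means the reference unit leads.  Cross-trial products are never formed.

#' Jitter-correction configuration
#'
#' @param window_ms jitter window (default 25 ms); must tile the analysis
#'   window into whole windows.
#' @param mode `"analytic"` (closed-form expectation, the default) or
#'   `"monte_carlo"` (average over explicit jitter resamples; retained as a
#'   test oracle).
#' @param n_resamples Monte-Carlo resamples.
#' @param seed seed for Monte-Carlo draws.
#' @return A `jitter_config` list.
#' @export
jitter_config <- function(window_ms = 25, mode = c("analytic", "monte_carlo"),
                          n_resamples = 1000, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(window_ms > 0, n_resamples >= 1)
  structure(list(window_ms = window_ms, mode = mode,
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed)), class = "jitter_config")
}

ccg_lags <- function(max_lag) seq.int(-max_lag, max_lag)

new_ccg_curve <- function(ref, target, max_lag, N, M, lambda, bin_width_s) {
  structure(list(ref = ref, target = target,
                 lags_ms = ccg_lags(max_lag),
                 theta = N - abs(ccg_lags(max_lag)),
                 raw = NULL, jittered = NULL, corrected = NULL,
                 N = N, M = M, lambda = lambda, bin_width_s = bin_width_s),
            class = "ccg_curve")
}

unit_index <- function(binned, unit) {
  ix <- match(unit, binned$unit_ids)
  if (is.na(ix)) stop("unknown unit id: ", unit, call. = FALSE)
  ix
}

# Spike bin positions of one unit on a concatenated trial axis with a
# cross-trial gap > max_lag, sorted ascending.
concat_positions <- function(binned, uix, stride) {
  xs <- matrix(binned$x[uix, , ], nrow = binned$M)
  hit <- which(xs == 1L, arr.ind = TRUE)
  if (!nrow(hit)) return(integer())
  sort((hit[, 1] - 1L) * stride + hit[, 2])
}

normalize_ccg_counts <- function(counts, M, theta, lambda_j, lambda_k) {
  counts / (M * theta * sqrt(lambda_j * lambda_k))
}

#' Raw cross-correlogram
#'
#' Firing-rate-normalized cross-correlogram of a unit pair over lags
#' -max_lag..+max_lag ms, per the formula in the package overview.  The pair
#' is canonicalized internally so that `raw_ccg(b, j, k)` and
#' `raw_ccg(b, k, j)` are exact lag-mirrors of each other.
#'
#' @param binned a `binned_spikes` object (1 ms bins assumed for the ms lag
#'   axis).
#' @param j,k reference and target unit ids.
#' @param max_lag_ms lag range (default 100, required by the 50-100 ms flank
#'   noise window).
#' @return A `ccg_curve` with `raw` and `theta` populated.
#' @export
raw_ccg <- function(binned, j, k, max_lag_ms = 100) {
  stopifnot(inherits(binned, "binned_spikes"))
  ji <- unit_index(binned, j); ki <- unit_index(binned, k)
  lam <- binned$lambda[c(ji, ki)]
  if (any(lam <= 0)) stop("zero-rate unit in pair; pre-filter units",
                          call. = FALSE)
  max_lag <- as.integer(max_lag_ms)
  if (binned$N <= max_lag) stop("analysis window shorter than the lag range")
  mirror <- ji > ki
  if (mirror) { tmp <- ji; ji <- ki; ki <- tmp }
  stride <- binned$N + max_lag + 1L
  counts <- sparse_xcorr_counts(concat_positions(binned, ji, stride),
                                concat_positions(binned, ki, stride), max_lag)
  curve <- new_ccg_curve(j, k, max_lag, binned$N, binned$M,
                         binned$lambda[c(unit_index(binned, j),
                                         unit_index(binned, k))],
                         binned$bin_width_s)
  ccg <- normalize_ccg_counts(counts, binned$M, curve$theta,
                              lam[1], lam[2])
  curve$raw <- if (mirror) rev(ccg) else ccg
  curve
}

# Expected jittered rate array (M x N) for one unit: within each jitter
# window of each trial, the trial's spike count is distributed over bins
# proportionally to the across-trial PSTH; windows with zero PSTH mass but a
# nonzero count (reachable only through clipping pathologies) distribute the
# count uniformly.
jitter_expected_rate <- function(binned, uix, win_bins) {
  xs <- binned$x[uix, , , drop = TRUE]
  if (binned$M == 1L) xs <- matrix(xs, nrow = 1L)
  N <- binned$N
  W <- N %/% win_bins
  wid <- rep(seq_len(W), each = win_bins)
  psth <- colMeans(xs)
  wsum <- as.numeric(rowsum(psth, wid))
  q <- ifelse(wsum[wid] > 0, psth / wsum[wid], 1 / win_bins)
  counts <- t(rowsum(t(xs), wid))            # M x W window counts
  counts[, wid, drop = FALSE] * rep(q, each = binned$M)
}

# One explicit jitter resample of a unit's spike trains: per trial-window,
# redraw each spike's bin with probability proportional to the PSTH within
# the window.  Returns count positions on the concatenated axis (duplicates
# allowed; counts, not binary, so the resample mean matches the analytic
# expectation).
jitter_resample_positions <- function(binned, uix, win_bins, stride) {
  xs <- binned$x[uix, , , drop = TRUE]
  if (binned$M == 1L) xs <- matrix(xs, nrow = 1L)
  N <- binned$N
  W <- N %/% win_bins
  wid <- rep(seq_len(W), each = win_bins)
  psth <- colMeans(xs)
  pos <- vector("list", binned$M)
  for (i in seq_len(binned$M)) {
    row <- xs[i, ]
    newbins <- integer(sum(row))
    n0 <- 0L
    for (w in seq_len(W)) {
      bins <- ((w - 1L) * win_bins + 1L):(w * win_bins)
      n <- sum(row[bins])
      if (n == 0L) next
      pw <- psth[bins]
      if (sum(pw) <= 0) pw <- rep(1, win_bins)
      newbins[(n0 + 1L):(n0 + n)] <- sample(bins, n, replace = TRUE,
                                            prob = pw)
      n0 <- n0 + n
    }
    pos[[i]] <- (i - 1L) * stride + newbins
  }
  sort(unlist(pos))
}

check_jitter_window <- function(binned, jitter) {
  win_bins <- as.integer(round(jitter$window_ms / 1000 / binned$bin_width_s))
  if (win_bins < 1 || binned$N %% win_bins != 0L) {
    stop("jitter window must tile the analysis window into whole windows",
         call. = FALSE)
  }
  win_bins
}

#' Jitter-expected cross-correlogram
#'
#' The expected CCG under the interval-jitter null that preserves each
#' trial's spike count within every jitter window and the across-trial PSTH.
#' Because both trains are jittered independently, the expectation factorizes
#' and the analytic mode simply applies the CCG formula to the two expected
#' jittered rate arrays.  Monte-Carlo mode averages the raw CCG over explicit
#' jitter resamples of both trains and exists as an independent oracle for
#' the analytic expression.
#'
#' @inheritParams raw_ccg
#' @param jitter a [jitter_config()].
#' @return A `ccg_curve` with `jittered` populated.
#' @export
jitter_expected_ccg <- function(binned, j, k, jitter = jitter_config(),
                                max_lag_ms = 100) {
  stopifnot(inherits(binned, "binned_spikes"), inherits(jitter, "jitter_config"))
  win_bins <- check_jitter_window(binned, jitter)
  ji <- unit_index(binned, j); ki <- unit_index(binned, k)
  lam <- binned$lambda[c(ji, ki)]
  if (any(lam <= 0)) stop("zero-rate unit in pair; pre-filter units",
                          call. = FALSE)
  max_lag <- as.integer(max_lag_ms)
  mirror <- ji > ki
  a <- min(ji, ki); b <- max(ji, ki)
  curve <- new_ccg_curve(j, k, max_lag, binned$N, binned$M, lam,
                         binned$bin_width_s)
  if (jitter$mode == "analytic") {
    L_trial <- next_smooth(binned$N + max_lag + 1L)
    L <- binned$M * L_trial
    pad <- function(r) {
      m <- matrix(0, L_trial, binned$M)
      m[seq_len(binned$N), ] <- t(r)
      as.numeric(m)
    }
    fa <- fft(pad(jitter_expected_rate(binned, a, win_bins)))
    fb <- fft(pad(jitter_expected_rate(binned, b, win_bins)))
    num <- fft_xcorr(fa, fb, L, max_lag)
  } else {
    set.seed(jitter$seed)
    stride <- binned$N + max_lag + 1L
    acc <- numeric(2L * max_lag + 1L)
    for (r in seq_len(jitter$n_resamples)) {
      pa <- jitter_resample_positions(binned, a, win_bins, stride)
      pb <- jitter_resample_positions(binned, b, win_bins, stride)
      acc <- acc + sparse_xcorr_counts(pa, pb, max_lag)
    }
    num <- acc / jitter$n_resamples
  }
  jit <- normalize_ccg_counts(num, binned$M, curve$theta,
                              binned$lambda[a], binned$lambda[b])
  curve$jittered <- if (mirror) rev(jit) else jit
  curve
}

#' Monte-Carlo jittered CCGs for all pairs (test oracle)
#'
#' Draws `n_resamples` joint jitter resamples of every unit's spike trains
#' and accumulates, for every unordered pair, the per-lag mean and standard
#' deviation of the resampled raw CCG.  One resample of each unit is shared
#' across all pairs, which keeps the oracle affordable; the mean converges
#' to the analytic expectation of [jitter_expected_ccg()].
#'
#' @inheritParams raw_ccg
#' @param jitter a [jitter_config()] (its `n_resamples` and `seed` are used).
#' @return list(pairs = data frame (a, b unit ids), mean, sd = pair x lag
#'   matrices, lags_ms, n_resamples).
#' @export
monte_carlo_jitter_ccgs <- function(binned, jitter = jitter_config(mode = "monte_carlo"),
                                    max_lag_ms = 100) {
  stopifnot(inherits(binned, "binned_spikes"))
  win_bins <- check_jitter_window(binned, jitter)
  U <- length(binned$unit_ids)
  max_lag <- as.integer(max_lag_ms)
  stride <- binned$N + max_lag + 1L
  theta <- binned$N - abs(ccg_lags(max_lag))
  prs <- combn(U, 2)
  n_pairs <- ncol(prs)
  n_lags <- 2L * max_lag + 1L
  norm <- matrix(0, n_pairs, n_lags)
  for (i in seq_len(n_pairs)) {
    lam <- binned$lambda[prs[, i]]
    norm[i, ] <- 1 / (binned$M * theta * sqrt(lam[1] * lam[2]))
  }
  s1 <- matrix(0, n_pairs, n_lags)
  s2 <- matrix(0, n_pairs, n_lags)
  set.seed(jitter$seed)
  for (r in seq_len(jitter$n_resamples)) {
    pos <- lapply(seq_len(U), function(u) {
      jitter_resample_positions(binned, u, win_bins, stride)
    })
    for (i in seq_len(n_pairs)) {
      cc <- sparse_xcorr_counts(pos[[prs[1, i]]], pos[[prs[2, i]]],
                                max_lag) * norm[i, ]
      s1[i, ] <- s1[i, ] + cc
      s2[i, ] <- s2[i, ] + cc^2
    }
  }
  mu <- s1 / jitter$n_resamples
  vr <- pmax(s2 / jitter$n_resamples - mu^2, 0)
  list(pairs = data.frame(a = binned$unit_ids[prs[1, ]],
                          b = binned$unit_ids[prs[2, ]]),
       mean = mu, sd = sqrt(vr * jitter$n_resamples /
                              max(1, jitter$n_resamples - 1)),
       lags_ms = ccg_lags(max_lag), n_resamples = jitter$n_resamples)
}

#' Jitter-corrected cross-correlogram
#'
#' Elementwise `corrected = raw - jittered`.
#'
#' @param raw_curve,jittered_curve `ccg_curve` objects on identical lag axes
#'   for the same ordered pair.
#' @return A `ccg_curve` with all three variants populated.
#' @export
corrected_ccg <- function(raw_curve, jittered_curve) {
  if (!identical(raw_curve$lags_ms, jittered_curve$lags_ms) ||
      !identical(c(raw_curve$ref, raw_curve$target),
                 c(jittered_curve$ref, jittered_curve$target))) {
    stop("lag axes or pair identity mismatch", call. = FALSE)
  }
  out <- raw_curve
  out$jittered <- jittered_curve$jittered
  out$corrected <- out$raw - out$jittered
  out
}

#' Mirror a CCG curve to the opposite ordering
#'
#' Enforces the identity CCG_{j-k}(tau) = CCG_{k-j}(-tau) exactly, without
#' recomputation.
#'
#' @param curve a `ccg_curve`.
#' @return The curve for the reversed pair ordering.
#' @export
mirror_ccg <- function(curve) {
  out <- curve
  out$ref <- curve$target
  out$target <- curve$ref
  out$lambda <- rev(curve$lambda)
  for (f in c("raw", "jittered", "corrected")) {
    if (!is.null(curve[[f]])) out[[f]] <- rev(curve[[f]])
  }
  out
}

peak_features_from_curve <- function(corrected, lags_ms, max_peak_lag_ms = 10,
                                     noise_range_ms = c(50, 100),
                                     threshold_sd = 7) {
  stopifnot(!is.null(corrected))
  inwin <- abs(lags_ms) <= max_peak_lag_ms
  noise <- abs(lags_ms) >= noise_range_ms[1] &
    abs(lags_ms) <= noise_range_ms[2]
  noise_mean <- mean(corrected[noise])
  noise_sd <- sd(corrected[noise])
  # tie-break: smallest |tau| first, then negative tau
  ord <- order(abs(lags_ms[inwin]), lags_ms[inwin])
  cand <- which(inwin)[ord]
  pk <- cand[which.max(corrected[cand])]
  tr <- cand[which.min(corrected[cand])]
  global_max_in <- max(corrected) <= corrected[pk]
  global_min_in <- min(corrected) >= corrected[tr]
  z_ok <- is.finite(noise_sd) && noise_sd > 0
  z_peak <- if (z_ok) (corrected[pk] - noise_mean) / noise_sd else NA_real_
  z_trough <- if (z_ok) (corrected[tr] - noise_mean) / noise_sd else NA_real_
  list(peak_lag_ms = lags_ms[pk], peak_efficacy = corrected[pk],
       trough_lag_ms = lags_ms[tr], trough_value = corrected[tr],
       noise_mean = noise_mean, noise_sd = noise_sd,
       z_peak = z_peak, z_trough = z_trough,
       significant = z_ok && z_peak > threshold_sd && global_max_in,
       significant_trough = z_ok && z_trough < -threshold_sd && global_min_in,
       degenerate_noise = !z_ok)
}

#' Peak and trough features of a corrected CCG
#'
#' The peak is the maximum of the corrected CCG within `max_peak_lag_ms` of
#' zero (ties broken toward smaller |tau|, then toward negative tau).  Noise
#' statistics come from the corrected-CCG flanks (50 <= |tau| <= 100 ms by
#' default).  A pair is significant when the peak exceeds `threshold_sd`
#' standard deviations above the flank mean *and* the global maximum of the
#' corrected CCG lies within the lag window.  Trough features are computed
#' symmetrically (z below `-threshold_sd`) for inhibitory-style counts.
#'
#' @param ccg_curve a `ccg_curve` with `corrected` populated over +-100 ms.
#' @param max_peak_lag_ms lag window for the peak (default 10).
#' @param noise_range_ms flank range for the noise distribution.
#' @param threshold_sd significance threshold in flank SDs (default 7).
#' @return A `peak_features` list; `degenerate_noise = TRUE` flags pairs with
#'   zero flank SD, whose significance is undefined.
#' @export
detect_peak <- function(ccg_curve, max_peak_lag_ms = 10,
                        noise_range_ms = c(50, 100), threshold_sd = 7) {
  stopifnot(inherits(ccg_curve, "ccg_curve"))
  out <- peak_features_from_curve(ccg_curve$corrected, ccg_curve$lags_ms,
                                  max_peak_lag_ms, noise_range_ms,
                                  threshold_sd)
  structure(c(list(ref = ccg_curve$ref, target = ccg_curve$target), out),
            class = "peak_features")
}

#' Screen unit pairs for spike-sorting double counts
#'
#' For pairs of units closer than `dist_um` in depth, computes the fraction
#' of the smaller train's spikes that have a partner spike of the other unit
#' within `coincidence_ms` in the same trial; pairs exceeding `frac` are
#' flagged as putative double-counted (split) units.  Requires sub-
#' millisecond spike times, so it operates on the spike table, not on binned
#' data.
#'
#' @param spikes,units dataset tables.
#' @param dist_um depth-distance screen (default 50).
#' @param coincidence_ms coincidence window (default 0.167).
#' @param frac flagging threshold on the overlap fraction (default 0.20).
#' @return Data frame `ref, target, distance_um, overlap_frac, flagged`, one
#'   row per unordered unit pair (overlap_frac is `NA` for exempt pairs).
#' @export
screen_double_counts <- function(spikes, units, dist_um = 50,
                                 coincidence_ms = 0.167, frac = 0.20) {
  ids <- sort(units$unit_id)
  if (length(ids) < 2) {
    return(data.frame(ref = integer(), target = integer(),
                      distance_um = numeric(), overlap_frac = numeric(),
                      flagged = logical()))
  }
  depth <- units$depth_um[match(ids, units$unit_id)]
  # absolute per-trial time axis so coincidences never span trials
  toff <- (match(spikes$trial_id, sort(unique(spikes$trial_id))) - 1) * 1e6
  times <- split(spikes$time_s + toff, spikes$unit_id)
  prs <- combn(length(ids), 2)
  n <- ncol(prs)
  overlap <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    a <- ids[prs[1, i]]; b <- ids[prs[2, i]]
    if (abs(depth[prs[1, i]] - depth[prs[2, i]]) >= dist_um) next
    ta <- sort(times[[as.character(a)]]); tb <- sort(times[[as.character(b)]])
    if (is.null(ta) || is.null(tb) || !length(ta) || !length(tb)) {
      overlap[i] <- 0
      next
    }
    if (length(tb) < length(ta)) { tmp <- ta; ta <- tb; tb <- tmp }
    eps <- coincidence_ms / 1000
    hit <- findInterval(ta + eps, tb) > findInterval(ta - eps, tb)
    overlap[i] <- mean(hit)
  }
  data.frame(ref = ids[prs[1, ]], target = ids[prs[2, ]],
             distance_um = abs(depth[prs[1, ]] - depth[prs[2, ]]),
             overlap_frac = overlap,
             flagged = !is.na(overlap) & overlap > frac)
}

#' Compute corrected CCGs and peak features for every unit pair
#'
#' Batch driver: for every unordered pair of units in `binned`, computes the
#' raw, jitter-expected (analytic), and corrected CCGs, extracts peak and
#' trough features, and attaches depth distance and layer pairing.  Both
#' orderings are represented: features of the reversed ordering follow from
#' the exact mirror identity and are not recomputed.  Pairs flagged by
#' [screen_double_counts()] are marked and, by default, excluded from the
#' significant set.
#'
#' @param binned a `binned_spikes` object (after rate filtering).
#' @param units unit table (for depth and layer).
#' @param jitter a [jitter_config()]; the analytic mode is used regardless
#'   for speed.
#' @param max_lag_ms lag range (default 100).
#' @param threshold_sd,max_peak_lag_ms significance parameters (7 SD, 10 ms).
#' @param double_flags optional result of [screen_double_counts()].
#' @param exclude_flagged drop flagged pairs from the significant set
#'   (default TRUE; they remain in the table with their flag).
#' @param keep_curves store the corrected curve matrix (needed for shape
#'   classification).
#' @return A `ccg_set`: list with `pairs` (one row per unordered pair,
#'   reference = smaller unit id), `lags_ms`, and `corrected` (pairs x lags
#'   matrix, if kept).
#' @export
compute_all_pairs <- function(binned, units, jitter = jitter_config(),
                              max_lag_ms = 100, threshold_sd = 7,
                              max_peak_lag_ms = 10, double_flags = NULL,
                              exclude_flagged = TRUE, keep_curves = TRUE) {
  stopifnot(inherits(binned, "binned_spikes"))
  U <- length(binned$unit_ids)
  if (U < 2) stop("need at least 2 units after filtering", call. = FALSE)
  win_bins <- check_jitter_window(binned, jitter)
  max_lag <- as.integer(max_lag_ms)
  N <- binned$N; M <- binned$M
  stride <- N + max_lag + 1L
  L_trial <- next_smooth(N + max_lag + 1L)
  L <- M * L_trial
  theta <- N - abs(ccg_lags(max_lag))

  pos <- lapply(seq_len(U), function(u) concat_positions(binned, u, stride))
  fjit <- vector("list", U)
  for (u in seq_len(U)) {
    m <- matrix(0, L_trial, M)
    m[seq_len(N), ] <- t(jitter_expected_rate(binned, u, win_bins))
    fjit[[u]] <- fft(as.numeric(m))
  }

  prs <- combn(U, 2)
  n_pairs <- ncol(prs)
  lags <- ccg_lags(max_lag)
  corrected <- if (keep_curves) matrix(NA_real_, n_pairs, length(lags))
  rows <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    a <- prs[1, i]; b <- prs[2, i]
    lam <- binned$lambda[c(a, b)]
    counts <- sparse_xcorr_counts(pos[[a]], pos[[b]], max_lag)
    raw <- normalize_ccg_counts(counts, M, theta, lam[1], lam[2])
    jit <- normalize_ccg_counts(fft_xcorr(fjit[[a]], fjit[[b]], L, max_lag),
                                M, theta, lam[1], lam[2])
    corr <- raw - jit
    if (keep_curves) corrected[i, ] <- corr
    pf <- peak_features_from_curve(corr, lags, max_peak_lag_ms,
                                   threshold_sd = threshold_sd)
    rows[[i]] <- data.frame(
      ref = binned$unit_ids[a], target = binned$unit_ids[b],
      peak_lag_ms = pf$peak_lag_ms, peak_efficacy = pf$peak_efficacy,
      z_peak = pf$z_peak, z_trough = pf$z_trough,
      trough_lag_ms = pf$trough_lag_ms,
      significant = pf$significant,
      significant_trough = pf$significant_trough,
      degenerate_noise = pf$degenerate_noise)
  }
  pairs <- do.call(rbind, rows)

  di <- match(pairs$ref, units$unit_id)
  dk <- match(pairs$target, units$unit_id)
  pairs$distance_um <- abs(units$depth_um[di] - units$depth_um[dk])
  pairs$layer_ref <- as.character(units$layer[di])
  pairs$layer_target <- as.character(units$layer[dk])

  pairs$flagged_double <- FALSE
  if (!is.null(double_flags)) {
    key <- paste(pmin(pairs$ref, pairs$target), pmax(pairs$ref, pairs$target))
    fkey <- paste(pmin(double_flags$ref, double_flags$target),
                  pmax(double_flags$ref, double_flags$target))
    hit <- match(key, fkey)
    pairs$flagged_double <- !is.na(hit) & double_flags$flagged[hit]
    if (exclude_flagged) {
      pairs$significant <- pairs$significant & !pairs$flagged_double
    }
  }

  structure(list(pairs = pairs, lags_ms = lags, corrected = corrected,
                 threshold_sd = threshold_sd,
                 max_peak_lag_ms = max_peak_lag_ms,
                 M = M, N = N), class = "ccg_set")
}

#' @export
print.ccg_set <- function(x, ...) {
  cat(sprintf("ccg_set: %d pairs, %d significant (%.1f%%), %d with significant troughs\n",
              nrow(x$pairs), sum(x$pairs$significant),
              100 * mean(x$pairs$significant),
              sum(x$pairs$significant_trough)))
  invisible(x)
}
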