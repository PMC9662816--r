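# The hand-checkable fixture and the mirror identity are covered again at
# acceptance level; here they guard the unit contracts alongside the
# internals (expected jitter rates, peak tie-breaks, double-count screen).

hand_binned <- function() {
  trials <- data.frame(trial_id = 1, direction_deg = 0, spatial_freq_cpd = 2,
                       onset_s = 0, duration_s = 0.006)
  units <- data.frame(unit_id = 1:2, depth_um = c(0, -20), layer = "5")
  sp <- data.frame(unit_id = c(1, 1, 2, 2), trial_id = 1,
                   time_s = c(0.0005, 0.0025, 0.0015, 0.0035))
  bin_spikes(sp, trials, units, window = c(0, 0.006))
}

test_that("raw CCG matches the normalized coincidence formula", {
  b <- hand_binned()
  cv <- raw_ccg(b, 1, 2, max_lag_ms = 5)
  expect_equal(cv$raw[cv$lags_ms == 1], 1.2)
  expect_equal(cv$raw[cv$lags_ms == -1], 0.6)
  expect_identical(cv$theta[cv$lags_ms == 0], b$N)
  expect_identical(cv$theta, rev(cv$theta))
  expect_error(raw_ccg(b, 1, 2), "shorter than the lag range")
})

test_that("mirror symmetry is exact for raw, jittered, and corrected", {
  b <- poisson_binned(n_units = 3, n_trials = 8, rate_hz = 30, seed = 3,
                      window = c(0.4, 0.9))
  jc <- jitter_config()
  for (pr in list(c(1, 2), c(2, 3))) {
    f_raw <- raw_ccg(b, pr[1], pr[2])
    r_raw <- raw_ccg(b, pr[2], pr[1])
    expect_identical(f_raw$raw, rev(r_raw$raw))
    f_jit <- jitter_expected_ccg(b, pr[1], pr[2], jc)
    r_jit <- jitter_expected_ccg(b, pr[2], pr[1], jc)
    expect_identical(f_jit$jittered, rev(r_jit$jittered))
    f_cor <- corrected_ccg(f_raw, f_jit)
    expect_identical(f_cor$corrected,
                     rev(corrected_ccg(r_raw, r_jit)$corrected))
    expect_identical(mirror_ccg(f_cor)$corrected,
                     corrected_ccg(r_raw, r_jit)$corrected)
  }
  expect_error(raw_ccg(poisson_binned(2, 4, c(20, 0), seed = 1), 1, 2),
               "zero-rate")
})

test_that("expected jitter rate preserves window counts and PSTH shape", {
  # 25 identical trials, each with one spike at a distinct bin of the first
  # window: flat PSTH inside the window, count n = 1 per trial
  M <- 25; N <- 50
  x <- array(0L, dim = c(1, M, N))
  for (i in 1:M) x[1, i, i] <- 1L
  b <- structure(list(x = x, unit_ids = 1L, trial_ids = 1:M,
                      window = c(0, 0.05), bin_width_s = 0.001, M = M, N = N,
                      lambda = c(`1` = sum(x) / (M * N)),
                      clipped = c(`1` = 0L)), class = "binned_spikes")
  r <- ccgcolumn:::jitter_expected_rate(b, 1, 25L)
  expect_equal(dim(r), c(M, N))
  # flat PSTH in window 1 -> expected rate n/25 in each of its 25 bins
  expect_equal(unname(r[1, 1:25]), rep(1 / 25, 25))
  expect_equal(unname(r[1, 26:50]), rep(0, 25))
  # per-trial window counts are preserved in expectation
  expect_equal(rowSums(r), rowSums(matrix(x[1, , ], nrow = M)))

  expect_error(jitter_expected_ccg(hand_binned(), 1, 2, jitter_config(25)),
               "tile")
})

test_that("analytic jitter expectation matches the Monte-Carlo oracle", {
  set.seed(5)
  M <- 10; N <- 600; U <- 3
  tt <- (1:N) / N
  x <- array(0L, dim = c(U, M, N))
  for (u in 1:U) {
    rate <- 0.02 * (1 + 0.8 * sin(2 * pi * 3 * tt + u))
    x[u, , ] <- matrix(rbinom(M * N, 1, rep(rate, each = M)), M, N)
  }
  lam <- sapply(1:U, function(u) mean(x[u, , ]))
  b <- structure(list(x = x, unit_ids = 1:U, trial_ids = 1:M,
                      window = c(0.4, 1), bin_width_s = 0.001, M = M, N = N,
                      lambda = setNames(lam, 1:U), clipped = integer(U)),
                 class = "binned_spikes")
  mc <- monte_carlo_jitter_ccgs(b, jitter_config(mode = "monte_carlo",
                                                 n_resamples = 400, seed = 7))
  for (i in seq_len(nrow(mc$pairs))) {
    ja <- jitter_expected_ccg(b, mc$pairs$a[i], mc$pairs$b[i])
    se <- mc$sd[i, ] / sqrt(mc$n_resamples)
    expect_true(all(abs(ja$jittered - mc$mean[i, ]) < 4 * pmax(se, 1e-12)))
  }
})

test_that("corrected CCG subtracts and detects planted peaks", {
  b <- poisson_binned(n_units = 2, n_trials = 40, rate_hz = 20, seed = 9)
  rc <- raw_ccg(b, 1, 2)
  jc <- rc; jc$jittered <- rc$raw
  expect_equal(corrected_ccg(rc, jc)$corrected, rep(0, 201))
  jc2 <- jc; jc2$ref <- 2; jc2$target <- 1
  expect_error(corrected_ccg(rc, jc2), "mismatch")

  # planted monosynapse survives jitter correction at the planted delay
  ds <- poisson_dataset(n_units = 2, n_trials = 120, rate_hz = c(20, 14),
                        seed = 10)
  inj <- inject_monosynaptic(ds$spikes, ds$trials, 1, 2, 0.3, 3, 0, seed = 11)
  bb <- bin_spikes(inj$spikes, ds$trials, ds$units)
  cv <- corrected_ccg(raw_ccg(bb, 1, 2), jitter_expected_ccg(bb, 1, 2))
  pf <- detect_peak(cv)
  expect_identical(pf$peak_lag_ms, 3L)
  expect_true(pf$significant)
})

test_that("detect_peak applies the 7 SD / 10 ms rule and tie-breaks", {
  lags <- seq(-100, 100)
  noise_template <- rep(c(-0.001, 0.001), length.out = 201)

  peak_at <- function(lag, height) {
    y <- noise_template
    y[lags == lag] <- height
    fake_curve(y)
  }
  # z just above 7 at +3 ms -> significant
  f1 <- detect_peak(peak_at(3, 0.05))
  expect_identical(f1$peak_lag_ms, 3L)
  expect_true(f1$z_peak > 7 && f1$significant)
  # strong peak at 12 ms -> outside the lag window, not significant
  f2 <- detect_peak(peak_at(12, 0.08))
  expect_false(f2$significant)
  # symmetric curve with unique max at 0
  y3 <- 0.03 * exp(-0.5 * (lags / 4)^2)
  f3 <- detect_peak(fake_curve(y3))
  expect_identical(f3$peak_lag_ms, 0L)
  expect_equal(f3$peak_efficacy, 0.03)
  # exact tie at +-2 ms resolves toward negative tau
  y4 <- noise_template
  y4[lags %in% c(-2, 2)] <- 0.05
  expect_identical(detect_peak(fake_curve(y4))$peak_lag_ms, -2L)
  # zero flank SD flags significance as undefined
  y5 <- rep(0, 201); y5[lags == 0] <- 0.05
  f5 <- detect_peak(fake_curve(y5))
  expect_true(f5$degenerate_noise)
  expect_false(f5$significant)
})

test_that("sign-flipping maps peak z to trough z exactly", {
  for (seed in 1:3) {
    y <- bump_curve(2, 2, amp = 0.03, noise_sd = 0.002, seed = seed)
    up <- detect_peak(fake_curve(y))
    dn <- detect_peak(fake_curve(-y))
    expect_equal(up$z_peak, -dn$z_trough)
    expect_identical(up$peak_lag_ms, dn$trough_lag_ms)
    expect_identical(up$significant, dn$significant_trough)
  }
})

test_that("double-count screen flags split units and exempts distant pairs", {
  ds <- poisson_dataset(n_units = 2, n_trials = 30, rate_hz = 20,
                        depth_um = c(0, -20), seed = 12)
  # unit 3 duplicates unit 1 at the same depth
  dup <- ds$spikes[ds$spikes$unit_id == 1, ]
  dup$unit_id <- 3
  sp <- rbind(ds$spikes, dup)
  units <- rbind(ds$units[, 1:3],
                 data.frame(unit_id = 3, depth_um = 0, layer = "5"))
  fl <- screen_double_counts(sp, units)
  r13 <- fl[fl$ref == 1 & fl$target == 3, ]
  expect_equal(r13$overlap_frac, 1)
  expect_true(r13$flagged)
  # independent units at 20 um: coincidence fraction ~ 2*rate*window << 20%
  r12 <- fl[fl$ref == 1 & fl$target == 2, ]
  expect_lt(r12$overlap_frac, 0.05)
  expect_false(r12$flagged)
  # pairs separated by >= 50 um are exempt regardless of overlap
  units2 <- units; units2$depth_um <- c(0, -20, -60)
  fl2 <- screen_double_counts(sp, units2)
  expect_true(is.na(fl2$overlap_frac[fl2$ref == 1 & fl2$target == 3]))
  expect_false(fl2$flagged[fl2$ref == 1 & fl2$target == 3])
})

test_that("compute_all_pairs enumerates pairs and respects flags", {
  col <- generate_column(column_config(
    n_units = 6, n_repeats = 2,
    connections = list(n_monosynaptic = 1, n_common_input = 0), seed = 15))
  b <- filter_units_by_rate(bin_spikes(col$spikes, col$trials, col$units),
                            verbose = FALSE)
  cs <- compute_all_pairs(b, col$units)
  n <- length(b$unit_ids)
  expect_identical(nrow(cs$pairs), (n * (n - 1L)) %/% 2L)
  expect_true(all(cs$pairs$ref < cs$pairs$target))
  expect_identical(dim(cs$corrected), c(nrow(cs$pairs), 201L))

  # a pair computed via the batch path matches the single-pair path
  i <- which.max(cs$pairs$z_peak)
  cv <- corrected_ccg(raw_ccg(b, cs$pairs$ref[i], cs$pairs$target[i]),
                      jitter_expected_ccg(b, cs$pairs$ref[i],
                                          cs$pairs$target[i]))
  expect_equal(unname(cs$corrected[i, ]), cv$corrected, tolerance = 1e-10)

  # flagged pairs leave the significant set but keep their flag
  fl <- data.frame(ref = cs$pairs$ref[i], target = cs$pairs$target[i],
                   distance_um = 0, overlap_frac = 1, flagged = TRUE)
  cs2 <- compute_all_pairs(b, col$units, double_flags = fl)
  expect_true(cs2$pairs$flagged_double[i])
  expect_false(cs2$pairs$significant[i])
})
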