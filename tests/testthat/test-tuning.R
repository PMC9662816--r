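test_that("trial_responses computes windowed mean rates", {
  trials <- data.frame(trial_id = 1:2, direction_deg = c(0, 10),
                       spatial_freq_cpd = 2, onset_s = c(0, 1.25),
                       duration_s = 1)
  # 6 spikes inside the 30 ms-offset window -> 6 / 0.97 spikes/s
  sp <- data.frame(unit_id = 1, trial_id = 1,
                   time_s = c(0.01, seq(0.1, 0.6, by = 0.1)))
  r <- trial_responses(sp, trials)
  expect_equal(r$rate_hz[r$trial_id == 1], 6 / 0.97)
  # silent unit/trial -> 0
  expect_equal(r$rate_hz[r$trial_id == 2], 0)
})

test_that("tuning_curve averages, breaks ties toward 0, flags gaps", {
  trials <- data.frame(trial_id = 1:8,
                       direction_deg = rep(c(0, 90, 180, 270), 2),
                       spatial_freq_cpd = 2, onset_s = (0:7) * 1.25,
                       duration_s = 1)
  resp <- data.frame(unit_id = 1, trial_id = 1:8,
                     rate_hz = c(1, 5, 1, 1, 3, 5, 1, 1))
  p <- tuning_curve(resp, trials)[[1]]
  expect_equal(p$mean_response, c(2, 5, 1, 1))
  expect_equal(p$preferred_direction_deg, 90)

  # flat responses: tie broken toward the smallest angle
  flat <- data.frame(unit_id = 1, trial_id = 1:8, rate_hz = 2)
  expect_equal(tuning_curve(flat, trials)[[1]]$preferred_direction_deg, 0)

  # single repeat: the curve is that trial's responses
  one <- data.frame(unit_id = 1, trial_id = 1:4, rate_hz = c(4, 8, 15, 16))
  expect_equal(tuning_curve(one, trials[1:4, ])[[1]]$mean_response,
               c(4, 8, 15, 16))

  # missing direction errors with the gap listed
  expect_error(tuning_curve(resp[resp$trial_id %in% c(1, 2, 5, 6), ],
                            trials),
               "missing direction")
})

test_that("modulation ratio separates simple from complex responses", {
  trials <- data.frame(trial_id = 1:20, direction_deg = 0,
                       spatial_freq_cpd = 2, onset_s = (0:19) * 1.25,
                       duration_s = 1)

  # constant-rate unit: F1/F0 ~ 0 -> complex
  set.seed(31)
  spc <- do.call(rbind, lapply(1:20, function(i) {
    hit <- which(runif(1000) < 0.03)
    data.frame(unit_id = 1, trial_id = i,
               time_s = (hit - runif(length(hit))) / 1000)
  }))
  pc <- compute_tuning(spc, trials, stimulus_tf_hz = 4)[[1]]
  expect_lt(pc$modulation_ratio, 0.3)
  expect_identical(pc$cell_class, "complex")

  # half-wave rectified sinusoidal rate: F1/F0 = pi/2 -> simple
  set.seed(32)
  tt <- (1:1000 - 0.5) / 1000
  r <- 40 * pmax(0, sin(2 * pi * 4 * tt))
  sps <- do.call(rbind, lapply(1:20, function(i) {
    hit <- which(runif(1000) < r / 1000)
    data.frame(unit_id = 1, trial_id = i,
               time_s = (hit - runif(length(hit))) / 1000)
  }))
  ps <- compute_tuning(sps, trials, stimulus_tf_hz = 4)[[1]]
  expect_lt(abs(ps$modulation_ratio - pi / 2), 0.12)
  expect_identical(ps$cell_class, "simple")

  # the class rule is a strict inequality: exactly 1 maps to complex
  expect_identical(classify_modulation_ratio(1), "complex")
  expect_identical(classify_modulation_ratio(1 + 1e-9), "simple")
  expect_identical(classify_modulation_ratio(NA), "undefined")
})

test_that("signal correlation is affine-invariant and symmetric", {
  mk <- function(v) structure(list(unit_id = 1, directions_deg = seq(0, 350, 10),
                                   mean_response = v),
                              class = "tuning_profile")
  base <- sin(seq(0, 2 * pi, length.out = 36)) + 2
  a <- mk(base)
  b <- mk(2 * base + 5)
  expect_equal(signal_correlation(a, b)$r_ori, 1)
  d <- mk(-(base - mean(base)) + mean(base))
  expect_equal(signal_correlation(a, d)$r_ori, -1)
  # symmetry
  e <- mk(base + rnorm(36, 0, 0.1))
  expect_equal(signal_correlation(a, e)$r_ori, signal_correlation(e, a)$r_ori)
  # zero-variance vector flagged
  z <- mk(rep(3, 36))
  expect_true(is.na(signal_correlation(a, z)$r_ori))

  # two von Mises curves 90 degrees apart (kappa = 2) anticorrelate
  dirs <- seq(0, 350, 10)
  vm <- function(pref) exp(2 * (cos((dirs - pref) * pi / 180) - 1))
  expect_lt(signal_correlation(mk(vm(0)), mk(vm(90)))$r_ori, 0)
})

test_that("preferred direction recovers planted von Mises tuning", {
  # clean tuned world (no planted interactions) at default rates
  hits <- 0; total <- 0
  for (seed in c(11, 23)) {
    cfg <- column_config(n_units = 30, n_repeats = 10,
                         connections = list(n_monosynaptic = 0,
                                            n_common_input = 0), seed = seed)
    col <- generate_column(cfg)
    tb <- tuning_table(compute_tuning(col$spikes, col$trials,
                                      cfg$stimulus_tf_hz))
    gtu <- col$ground_truth$units
    m <- match(tb$unit_id, gtu$unit_id)
    err <- abs(((tb$preferred_direction_deg - gtu$true_pref_deg[m] + 180) %%
                  360) - 180)
    hits <- hits + sum(err <= 10); total <- total + length(err)
  }
  expect_gte(hits / total, 0.95)
})

test_that("mean r_ori increases with planted preferred-direction similarity", {
  cfg <- column_config(n_units = 30, tuning = list(kappa = 8, drive_hz = 20,
                                                   pref_scatter_deg = 40),
                       connections = list(n_monosynaptic = 0,
                                          n_common_input = 0), seed = 13)
  col <- generate_column(cfg)
  profs <- compute_tuning(col$spikes, col$trials, cfg$stimulus_tf_hz,
                          latency_offset_s = 0)
  rmat <- signal_correlation_matrix(profs)
  gtu <- col$ground_truth$units
  prs <- combn(nrow(gtu), 2)
  sim <- cos(2 * (gtu$true_pref_deg[prs[1, ]] -
                    gtu$true_pref_deg[prs[2, ]]) * pi / 180)
  r <- rmat[cbind(prs[1, ], prs[2, ])]
  # monotone association between tuning similarity and signal correlation
  expect_gt(cor(sim, r, method = "spearman"), 0.5)
  hi <- sim > quantile(sim, 2 / 3); lo <- sim < quantile(sim, 1 / 3)
  expect_gt(mean(r[hi]), mean(r[lo]))
})
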