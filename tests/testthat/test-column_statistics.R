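test_that("binned_relationship bins by quantiles with bootstrap CIs", {
  set.seed(1)
  x <- runif(500, 0, 1000)
  # constant y: every bin stat equals the constant with zero-width CI
  bc <- binned_relationship(x, rep(2.5, 500), seed = 1)
  expect_equal(bc$stat, rep(2.5, 10))
  expect_equal(bc$ci_hi - bc$ci_lo, rep(0, 10))
  # y = x: bin means strictly increasing
  bi <- binned_relationship(x, x, seed = 1)
  expect_true(all(diff(bi$stat) > 0))
  # heavy ties collapse bins with a warning
  expect_warning(binned_relationship(rep(c(1, 2), 250), rnorm(500), seed = 1),
                 "merged")
  expect_error(binned_relationship(1:5, 1:5, n_bins = 10), "at least")
})

test_that("fit_linear recovers noiseless slopes and MAE resists outliers", {
  x <- seq(0, 1000, length.out = 200)
  y <- 0.0026 * x + 1                       # 1.3 ms per 500 um
  f <- fit_linear(x, y, "MSE")
  expect_equal(f$slope, 0.0026, tolerance = 1e-10)
  expect_equal(f$intercept, 1, tolerance = 1e-8)
  expect_equal(fit_linear(x, rep(2, 200))$slope, 0)
  # one gross outlier: MAE slope stays near truth, MSE is dragged away
  y2 <- y; y2[100] <- 1000
  mse <- fit_linear(x, y2, "MSE")$slope
  mae <- fit_linear(x, y2, "MAE")$slope
  expect_lt(abs(mae - 0.0026), abs(mse - 0.0026))
  expect_error(fit_linear(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("fit_exponential_decay recovers planted half-distances", {
  x <- seq(10, 800, length.out = 60)
  y <- 0.04 * 2^(-x / 154)                  # half-distance 154 um
  f <- fit_exponential_decay(x, y)
  expect_equal(f$half_distance, 154, tolerance = 1e-3)
  expect_equal(f$amplitude, 0.04, tolerance = 1e-3)
  expect_false(f$no_decay)
  # constant y flags no-decay
  fc <- fit_exponential_decay(x, rep(0.02, 60))
  expect_true(fc$no_decay)
  expect_identical(fc$half_distance, Inf)
  expect_error(fit_exponential_decay(x, y - 0.02), "positive")
  # noisy recovery within 15%
  set.seed(7)
  yn <- pmax(1e-5, 0.04 * 2^(-x / 150) * exp(rnorm(60, 0, 0.15)))
  fn <- fit_exponential_decay(x, yn)
  expect_lt(abs(fn$half_distance - 150) / 150, 0.15)
})

test_that("distance matching pairs adjacent sorted distances", {
  pairs <- data.frame(distance_um = c(50, 10, 100, 12, 53),
                      peak_lag_ms = 1:5, peak_efficacy = (1:5) / 100,
                      r_ori = seq(0.1, 0.5, 0.1))
  suppressMessages(m <- distance_match(pairs))
  expect_identical(nrow(m$matches), 2L)
  expect_equal(sort(abs(m$matches$d_distance_um)), c(2, 3))
  expect_identical(m$n_dropped, 1L)
  # all-identical distances give zero differences
  same <- pairs; same$distance_um <- 7
  suppressMessages(ms <- distance_match(same))
  expect_equal(ms$matches$d_distance_um, rep(0, 2))
  expect_equal(ms$frac_close, 1)
})

test_that("planted distance-dependent delays surface in binned lag curves", {
  # spike-level check of the distance coupling: delays grow with depth
  # distance, so binned |peak lag| of significant pairs rises with distance
  cfg <- column_config(
    n_units = 36, seed = 61,
    connections = list(n_monosynaptic = 28, n_common_input = 0,
                       mono_delay_rate_ms_per_um = 0.008,
                       distance_scale_um = 400, tuning_weight = FALSE))
  col <- generate_column(cfg)
  b <- filter_units_by_rate(bin_spikes(col$spikes, col$trials, col$units),
                            verbose = FALSE)
  cs <- compute_all_pairs(b, col$units)
  sig <- cs$pairs[cs$pairs$significant, ]
  expect_gte(nrow(sig), 15)
  br <- binned_relationship(sig$distance_um, abs(sig$peak_lag_ms),
                            n_bins = 5, stat = "mean", seed = 1)
  expect_gt(cor(br$bin_center, br$stat, method = "spearman"), 0)
})

test_that("standardized regression recovers planted coefficients", {
  set.seed(11)
  n <- 2000
  d <- runif(n, 0, 500); r <- runif(n, -1, 1)
  zd <- as.numeric(scale(d)); zr <- as.numeric(scale(r))
  # noise-free generation: exact coefficients, R^2 = 1
  lag0 <- 2.48 + 0.94 * zd - 0.37 * zr
  f0 <- fit_standardized_regression(
    data.frame(distance_um = d, r_ori = r, peak_lag_ms = lag0,
               peak_efficacy = 0), "peak_lag")
  expect_equal(unname(f0$coefficients), c(0.94, -0.37), tolerance = 1e-6)
  expect_equal(f0$r_squared, 1, tolerance = 1e-9)

  # standardization absorbs affine predictor rescaling
  f0b <- fit_standardized_regression(
    data.frame(distance_um = d / 1000 + 3, r_ori = 10 * r,
               peak_lag_ms = lag0, peak_efficacy = 0), "peak_lag")
  expect_equal(f0b$coefficients, f0$coefficients, tolerance = 1e-6)

  # gross target outliers are neutralized by the 1.5 IQR rule
  lag1 <- lag0 + rnorm(n, 0, 0.5)
  lag1[1:20] <- 200
  f1 <- fit_standardized_regression(
    data.frame(distance_um = d, r_ori = r, peak_lag_ms = lag1,
               peak_efficacy = 0), "peak_lag")
  expect_gt(f1$removed, 0)
  expect_equal(unname(f1$coefficients), c(0.94, -0.37), tolerance = 0.08)
  expect_error(fit_standardized_regression(
    data.frame(distance_um = d, r_ori = d * 2, peak_lag_ms = lag0,
               peak_efficacy = 0), "peak_lag"), "collinear")
})

test_that("composition tests handle exact nulls", {
  # balanced table: chi-squared statistic 0, p = 1; proportion 0.5 gives z 0
  pairs <- data.frame(
    class_label = rep(c("S_sync", "F_async"), each = 100),
    layer_ref = rep(c("5", "6"), 100),
    layer_target = rep(c("5", "6", "6", "5"), 50),
    distance_um = runif(200, 0, 300), r_ori = rnorm(200, 0.3, 0.2))
  # construct exact 50/50 within-layer split per class
  pairs$layer_target <- pairs$layer_ref
  pairs$layer_target[seq(1, 200, by = 2)] <- "2/3"
  res <- class_composition_tests(pairs)
  expect_equal(res$within_layer$prop_within_layer, c(0.5, 0.5))
  expect_equal(res$within_layer$z, c(0, 0))
  expect_equal(res$chisq$statistic, 0)
  expect_equal(res$chisq$p_value, 1)
  # closed-form z for 30 forward of 40
  zt <- ccgcolumn:::one_proportion_z_test(30, 40)
  expect_equal(zt$z, (0.75 - 0.5) / sqrt(0.25 / 40))
  expect_lt(zt$p_value, 0.05)
})

test_that("layer logistic regression detects planted composition rules", {
  set.seed(21)
  n <- 400
  d <- runif(n, 86, 310)
  same <- rbinom(n, 1, 0.5)
  mk <- function(y) data.frame(
    class_label = ifelse(y == 1, "B_sync", "F_async"), distance_um = d,
    layer_ref = "5", layer_target = ifelse(same == 1, "5", "6"))
  # planted rule: same layer -> B_sync (with noise)
  y <- rbinom(n, 1, plogis(-1 + 2.5 * same))
  fit <- layer_logistic_regression(mk(y), "B_sync")
  expect_gt(fit$coefficients[["same_layer"]], 0)
  expect_lt(fit$p_values[["same_layer"]], 0.01)

  # simulated null: coefficients within 2 SE of zero in >= 90% of runs
  cover <- 0
  for (s in 1:60) {
    set.seed(1000 + s)
    y0 <- rbinom(n, 1, 0.3)
    f0 <- layer_logistic_regression(mk(y0), "B_sync")
    ok <- abs(f0$coefficients[["distance"]]) < 2 * f0$se[["distance"]] &&
      abs(f0$coefficients[["same_layer"]]) < 2 * f0$se[["same_layer"]]
    cover <- cover + ok
  }
  expect_gte(cover / 60, 0.9)

  expect_error(layer_logistic_regression(mk(y), "B_sync",
                                         distance_range = c(1000, 2000)),
               "fewer than 20")
})

test_that("simple-to-complex direction test counts forward vs reverse", {
  pairs <- data.frame(
    class_label = c(rep("F_async", 30), rep("R_async", 10)),
    cell_class_ref = "simple", cell_class_target = "complex")
  res <- simple_complex_direction_test(pairs)
  expect_identical(res$n_forward, 30L)
  expect_identical(res$n_reverse, 10L)
  expect_equal(res$z, (0.75 - 0.5) / sqrt(0.25 / 40))
  expect_lt(res$p_value, 0.05)
  # no qualifying pairs: empty result
  none <- pairs; none$cell_class_ref <- "complex"
  expect_identical(simple_complex_direction_test(none)$n_forward, 0L)
})

test_that("permuting class labels destroys planted composition effects", {
  set.seed(31)
  n <- 300
  same <- rbinom(n, 1, 0.5)
  pairs <- data.frame(
    class_label = ifelse(rbinom(n, 1, plogis(-1 + 3 * same)), "S_sync",
                         "F_async"),
    layer_ref = "5", layer_target = ifelse(same == 1, "5", "6"),
    distance_um = runif(n, 0, 300), r_ori = rnorm(n, 0.3, 0.2))
  obs <- class_composition_tests(pairs)
  expect_true(obs$within_layer$significant[
    obs$within_layer$class_label == "S_sync"])
  hits <- 0; B <- 120
  for (b in seq_len(B)) {
    perm <- pairs
    perm$class_label <- sample(perm$class_label)
    pw <- class_composition_tests(perm)$within_layer
    hits <- hits + any(pw$p_value < 0.05)
  }
  # two tests per permutation; Bonferroni-free family-wise bound ~ 0.10
  expect_lte(hits / B, 0.10 + 2 * sqrt(0.1 * 0.9 / B))
})
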