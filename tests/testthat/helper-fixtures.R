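# Shared fixture builders.  Everything is generated in code at test time.

# Minimal valid dataset: U units firing homogeneous Poisson at `rate_hz`
# over `n_trials` 1-second trials.
poisson_dataset <- function(n_units = 2, n_trials = 180, rate_hz = 20,
                            depth_um = NULL, seed = 1) {
  set.seed(seed)
  rate_hz <- rep_len(rate_hz, n_units)
  trials <- data.frame(trial_id = seq_len(n_trials),
                       direction_deg = rep_len(seq(0, 350, by = 10), n_trials),
                       spatial_freq_cpd = 2,
                       onset_s = (seq_len(n_trials) - 1) * 1.25,
                       duration_s = 1)
  sp <- do.call(rbind, lapply(seq_len(n_units), function(u) {
    n <- rpois(n_trials, rate_hz[u])
    if (sum(n) == 0) return(NULL)
    data.frame(unit_id = u, trial_id = rep(seq_len(n_trials), n),
               time_s = runif(sum(n)))
  }))
  if (is.null(sp)) sp <- data.frame(unit_id = integer(), trial_id = integer(),
                                    time_s = numeric())
  if (is.null(depth_um)) depth_um <- seq(0, by = -30, length.out = n_units)
  units <- data.frame(unit_id = seq_len(n_units), depth_um = depth_um,
                      layer = "5", mean_rate_hz = rate_hz)
  list(spikes = sp[order(sp$unit_id, sp$trial_id, sp$time_s), ],
       trials = trials, units = units)
}

poisson_binned <- function(n_units = 2, n_trials = 180, rate_hz = 20,
                           seed = 1, window = c(0.4, 1)) {
  ds <- poisson_dataset(n_units, n_trials, rate_hz, seed = seed)
  bin_spikes(ds$spikes, ds$trials, ds$units, window = window)
}

# Build a binned_spikes object directly from per-bin firing probabilities,
# bypassing the spike-table path for speed in large calibration runs.
# `probs` is a list with one element per unit: a scalar, a length-N vector,
# or an M x N matrix of Bernoulli probabilities per 1 ms bin.
binned_from_prob <- function(probs, M, N = 600, seed = 1,
                             window = c(0.4, 1)) {
  set.seed(seed)
  U <- length(probs)
  x <- array(0L, dim = c(U, M, N))
  for (u in seq_len(U)) {
    p <- probs[[u]]
    pm <- if (is.matrix(p)) p else matrix(p, M, N, byrow = !is.matrix(p) &&
                                            length(p) == N)
    x[u, , ] <- matrix(as.integer(runif(M * N) < pm), M, N)
  }
  lam <- vapply(seq_len(U), function(u) mean(x[u, , ]), numeric(1))
  structure(list(x = x, unit_ids = seq_len(U), trial_ids = seq_len(M),
                 window = window, bin_width_s = 0.001, M = M, N = N,
                 lambda = setNames(lam, seq_len(U)),
                 clipped = setNames(integer(U), seq_len(U))),
            class = "binned_spikes")
}

corrected_pair <- function(binned, j = 1, k = 2) {
  corrected_ccg(raw_ccg(binned, j, k), jitter_expected_ccg(binned, j, k))
}

# A ccg_curve shell with a chosen corrected vector, for peak-detector tests.
fake_curve <- function(corrected, max_lag = 100) {
  structure(list(ref = 1, target = 2, lags_ms = seq.int(-max_lag, max_lag),
                 theta = 600 - abs(seq(-max_lag, max_lag)),
                 raw = corrected, jittered = corrected * 0,
                 corrected = corrected, N = 600, M = 1,
                 lambda = c(`1` = 0.02, `2` = 0.02), bin_width_s = 0.001),
            class = "ccg_curve")
}

# Gaussian bump on the +-100 ms lag axis.
bump_curve <- function(center_ms, sd_ms, amp = 0.02, noise_sd = 0,
                       seed = NULL, max_lag = 100) {
  if (!is.null(seed)) set.seed(seed)
  lags <- seq(-max_lag, max_lag)
  y <- amp * exp(-0.5 * ((lags - center_ms) / sd_ms)^2)
  if (noise_sd > 0) y <- y + rnorm(length(y), 0, noise_sd)
  y
}

# Brute-force best 2-partition by within-cluster sum of squares.
brute_force_best_k2 <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  best <- NULL
  best_wcss <- Inf
  for (code in 1:(2^(n - 1) - 1)) {          # fix point 1 in cluster 1
    lab <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    if (length(unique(lab)) < 2) next
    wcss <- sum(vapply(split(seq_len(n), lab), function(ix) {
      sub <- points[ix, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
    if (wcss < best_wcss) { best_wcss <- wcss; best <- lab }
  }
  list(labels = best, wcss = best_wcss)
}

# Independent silhouette implementation (plain double loop) for oracle checks.
silhouette_oracle <- function(points, labels) {
  d <- as.matrix(dist(points))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- setdiff(which(labels == labels[i]), i)
    if (!length(same)) { s[i] <- 0; next }
    a <- mean(d[i, same])
    b <- min(sapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l])))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}
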