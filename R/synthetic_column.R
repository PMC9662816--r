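# Synthetic cortical column: trial-structured, orientation-tuned,
# depth-annotated spike trains with planted interactions and known ground
# truth.  Generator choices are test scaffolding and are deliberately
# segregated from the analysis code, which never sees the ground truth.

#' Default laminar thickness table
#'
#' Named vector of layer thicknesses in micrometers, ordered superficial to
#' deep.  The values are illustrative (histological estimates must be
#' user-supplied for real data); the anchor convention places depth 0 at the
#' layer 4c/5 border, i.e. at the top of layer "5".
#'
#' @return Named numeric vector of thicknesses (um).
#' @export
default_thickness_table <- function() {
  c("2/3" = 400, "4A/B" = 250, "4c_alpha" = 150, "4c_beta" = 150,
    "5" = 300, "6" = 400)
}

#' Configuration for the synthetic column generator
#'
#' Defaults emulate a single high-density penetration through an orientation
#' column: 36 drift directions in 10 degree steps, 1 s gratings repeated 5
#' times, ~20 Hz peak rates, a shared preferred orientation with small
#' scatter, a mix of simple (temporally modulated) and complex cells, an
#' onset transient, and slow shared rate modulation that the jitter null must
#' remove.  All interaction strengths live here, not in code.
#'
#' @param n_units number of units.
#' @param depth_range_um depth interval sampled uniformly (signed um,
#'   0 = 4c/5 border, negative deeper).
#' @param thickness_table laminar thickness table, see
#'   [default_thickness_table()].
#' @param n_directions,n_repeats grating directions (10 deg steps) and
#'   repeats per condition.
#' @param trial_duration_s stimulus duration (s); 0.25 s blank separates
#'   trials.
#' @param spatial_freq_cpd,stimulus_tf_hz grating spatial frequency and drift
#'   temporal frequency.
#' @param base_rate lognormal parameters (`meanlog`, `sdlog`) of the untuned
#'   background rate in spikes/s.
#' @param tuning list: von Mises concentration `kappa`, tuned drive amplitude
#'   `drive_hz` at the preferred direction, and `pref_scatter_deg` (SD of
#'   preferred directions around the column preference).
#' @param fraction_simple fraction of units given half-wave temporal
#'   modulation (F1/F0 > 1).
#' @param onset_transient list `amplitude` (multiplicative, >= 0) and
#'   `tau_s` decay constant of the stimulus-onset transient.
#' @param slow_mod list `timescale_s` (>= 0.1 so the 25 ms jitter window must
#'   remove it), `amplitude` (0 disables) and `n_groups` sharing one
#'   modulation.
#' @param connections list of planting parameters: `n_monosynaptic`,
#'   `mono_efficacy_p`, `mono_delay_range_ms`, `mono_jitter_sd_ms`,
#'   `n_common_input`, `ci_copy_p`, `ci_source_rate_hz`, `ci_jitter_sd_ms`,
#'   `ci_group_size`; optional distance coupling `mono_delay_rate_ms_per_um`
#'   (delay = 0.5 ms + rate x depth distance when > 0) and
#'   `efficacy_half_distance_um` (interaction strength halves per this
#'   distance; `Inf` disables); plus the pair-sampling kernel
#'   `distance_scale_um`
#'   (exponential decay of connection probability with depth distance) and
#'   `tuning_weight` (logical: weight by orientation similarity).
#' @param seed integer seed making the whole column reproducible.
#' @return A `column_config` list.
#' @export
column_config <- function(n_units = 120,
                          depth_range_um = c(-700, 950),
                          thickness_table = default_thickness_table(),
                          n_directions = 36,
                          n_repeats = 5,
                          trial_duration_s = 1,
                          spatial_freq_cpd = 2,
                          stimulus_tf_hz = 4,
                          base_rate = list(meanlog = log(8), sdlog = 0.4),
                          tuning = list(kappa = 8, drive_hz = 20,
                                        pref_scatter_deg = 15),
                          fraction_simple = 0.3,
                          onset_transient = list(amplitude = 2, tau_s = 0.05),
                          slow_mod = list(timescale_s = 0.2, amplitude = 0.3,
                                          n_groups = 2),
                          connections = list(),
                          seed = 1L) {
  conn_defaults <- list(n_monosynaptic = 30, mono_efficacy_p = 0.25,
                        mono_delay_range_ms = c(1, 4), mono_jitter_sd_ms = 0.5,
                        mono_delay_rate_ms_per_um = 0,
                        efficacy_half_distance_um = Inf,
                        n_common_input = 10, ci_copy_p = 0.5,
                        ci_source_rate_hz = 20, ci_jitter_sd_ms = 1,
                        ci_group_size = 2, distance_scale_um = 200,
                        tuning_weight = TRUE)
  connections <- utils::modifyList(conn_defaults, connections)
  cfg <- list(n_units = n_units, depth_range_um = depth_range_um,
              thickness_table = thickness_table, n_directions = n_directions,
              n_repeats = n_repeats, trial_duration_s = trial_duration_s,
              spatial_freq_cpd = spatial_freq_cpd,
              stimulus_tf_hz = stimulus_tf_hz, base_rate = base_rate,
              tuning = tuning, fraction_simple = fraction_simple,
              onset_transient = onset_transient, slow_mod = slow_mod,
              connections = connections, seed = as.integer(seed))
  validate_column_config(cfg)
  structure(cfg, class = "column_config")
}

validate_column_config <- function(cfg) {
  stopifnot(cfg$n_units >= 1, diff(cfg$depth_range_um) > 0,
            cfg$n_directions >= 1, cfg$n_repeats >= 1,
            cfg$trial_duration_s > 0, cfg$stimulus_tf_hz > 0)
  if (any(cfg$thickness_table <= 0)) stop("layer thicknesses must be positive")
  if (cfg$tuning$drive_hz < 0 || cfg$onset_transient$amplitude < 0 ||
      cfg$slow_mod$amplitude < 0) {
    stop("negative amplitudes are not allowed", call. = FALSE)
  }
  if (cfg$slow_mod$amplitude > 0 && cfg$slow_mod$timescale_s < 0.1) {
    stop("slow_mod timescale_s must be >= 0.1 s", call. = FALSE)
  }
  invisible(cfg)
}

wrap_deg <- function(x) ((x %% 360) + 360) %% 360

# Orientation similarity in [0, 1]: 1 for equal (or opposite) directions.
orientation_similarity <- function(a_deg, b_deg) {
  (cos(2 * (a_deg - b_deg) * pi / 180) + 1) / 2
}

#' Build per-unit stimulus-locked rate profiles
#'
#' Computes, for every unit and drift direction, the deterministic rate
#' profile rate(t) = base + drive * vonMises(direction - preferred; kappa),
#' with simple units' tuned drive multiplied by a mean-preserving half-wave
#' rectified sinusoid at the grating temporal frequency (F1/F0 = pi/2 for a
#' pure half-wave response) and an optional multiplicative onset transient.
#' Slow shared modulation is applied per trial at sampling time, not here,
#' because it is not stimulus-locked.
#'
#' @param config a `column_config`.
#' @return A `rate_profiles` list: `rate` array (unit x direction x 1 ms
#'   bins, spikes/s), `directions_deg`, `pref_deg`, `simple`,
#'   `base_rate_hz`, `slow_group`, `config`.
#' @export
make_rate_profiles <- function(config) {
  validate_column_config(config)
  set.seed(child_seed(config$seed, "profiles"))
  U <- config$n_units
  dirs <- seq(0, 360 - 360 / config$n_directions,
              by = 360 / config$n_directions)
  Tn <- as.integer(round(config$trial_duration_s * 1000))
  tt <- (seq_len(Tn) - 0.5) / 1000

  column_pref <- runif(1, 0, 360)
  pref <- wrap_deg(column_pref + rnorm(U, 0, config$tuning$pref_scatter_deg))
  simple <- runif(U) < config$fraction_simple
  base <- rlnorm(U, config$base_rate$meanlog, config$base_rate$sdlog)
  slow_group <- if (config$slow_mod$amplitude > 0) {
    sample(rep_len(seq_len(config$slow_mod$n_groups), U))
  } else rep(0L, U)

  # temporal factors, mean-preserving over the trial
  hw <- pmax(0, sin(2 * pi * config$stimulus_tf_hz * tt))
  hw <- hw / mean(hw)
  transient <- 1 + config$onset_transient$amplitude *
    exp(-tt / config$onset_transient$tau_s)

  rate <- array(0, dim = c(U, length(dirs), Tn))
  for (u in seq_len(U)) {
    tune <- config$tuning$drive_hz *
      exp(config$tuning$kappa * (cos((dirs - pref[u]) * pi / 180) - 1))
    # simple cells fire in phase with the grating: the whole response is
    # half-wave modulated (F1/F0 = pi/2), not just the tuned drive
    temporal <- if (simple[u]) hw else rep(1, Tn)
    rate[u, , ] <- outer(tune + base[u], temporal)
    rate[u, , ] <- sweep(rate[u, , , drop = FALSE], 3, transient, `*`)[1, , ]
  }
  rate[rate < 0] <- 0
  structure(list(rate = rate, directions_deg = dirs, pref_deg = pref,
                 simple = simple, base_rate_hz = base,
                 slow_group = slow_group, config = config),
            class = "rate_profiles")
}

empty_ground_truth <- function(units_truth = NULL) {
  structure(list(
    connections = data.frame(kind = character(), pre = integer(),
                             post = integer(), delay_ms = numeric(),
                             efficacy_p = numeric(), jitter_sd_ms = numeric(),
                             source_rate_hz = numeric()),
    units = units_truth), class = "ground_truth")
}

gt_add <- function(gt, kind, pre, post, delay_ms, efficacy_p, jitter_sd_ms,
                   source_rate_hz = NA_real_) {
  gt$connections <- rbind(gt$connections, data.frame(
    kind = kind, pre = pre, post = post, delay_ms = delay_ms,
    efficacy_p = efficacy_p, jitter_sd_ms = jitter_sd_ms,
    source_rate_hz = source_rate_hz))
  gt
}

#' Inject a monosynaptic connection into a spike table
#'
#' Every presynaptic spike triggers a postsynaptic spike with probability
#' `efficacy_p` at lag `delay_ms` plus zero-mean Gaussian noise with SD
#' `jitter_sd_ms`.  Background spikes are never removed; triggered spikes
#' falling outside the trial are dropped.
#'
#' @param spikes,trials data frames per the dataset schema.
#' @param pre_unit,post_unit unit ids (must differ).
#' @param efficacy_p per-spike transmission probability in \[0, 1\].
#' @param delay_ms synaptic delay (> 0).
#' @param jitter_sd_ms SD of the delay noise (>= 0).
#' @param seed optional seed; `NULL` inherits the current RNG stream.
#' @param ground_truth optional `ground_truth` to append to.
#' @return list(spikes, ground_truth).
#' @export
inject_monosynaptic <- function(spikes, trials, pre_unit, post_unit,
                                efficacy_p, delay_ms, jitter_sd_ms = 0,
                                seed = NULL, ground_truth = NULL) {
  if (pre_unit == post_unit) stop("pre_unit must differ from post_unit")
  if (delay_ms <= 0) stop("delay_ms must be positive")
  if (jitter_sd_ms < 0) stop("jitter_sd_ms must be non-negative")
  stopifnot(efficacy_p >= 0, efficacy_p <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ground_truth)) ground_truth <- empty_ground_truth()
  ground_truth <- gt_add(ground_truth, "monosynaptic", pre_unit, post_unit,
                         delay_ms, efficacy_p, jitter_sd_ms)
  if (efficacy_p > 0) {
    pre <- spikes[spikes$unit_id == pre_unit, , drop = FALSE]
    fire <- runif(nrow(pre)) < efficacy_p
    if (any(fire)) {
      tnew <- pre$time_s[fire] + delay_ms / 1000 +
        rnorm(sum(fire), 0, jitter_sd_ms / 1000)
      dur <- trials$duration_s[match(pre$trial_id[fire], trials$trial_id)]
      ok <- tnew >= 0 & tnew <= dur
      if (any(ok)) {
        spikes <- rbind(spikes, data.frame(unit_id = post_unit,
                                           trial_id = pre$trial_id[fire][ok],
                                           time_s = tnew[ok]))
        spikes <- spikes[order(spikes$unit_id, spikes$trial_id,
                               spikes$time_s), ]
        rownames(spikes) <- NULL
      }
    }
  }
  list(spikes = spikes, ground_truth = ground_truth)
}

#' Inject common input into a group of units
#'
#' A hidden Poisson source is drawn per trial; each member unit receives each
#' source spike with probability `copy_p` at a lag drawn as zero-mean
#' Gaussian noise with SD `jitter_sd_ms`.  With small jitter this plants a
#' sharp zero-lag CCG peak; larger jitter broadens it (corrected-CCG peak
#' width grows with sqrt(2) * jitter SD).
#'
#' @param spikes,trials data frames per the dataset schema.
#' @param members vector of >= 2 unit ids.
#' @param source_rate_hz rate of the hidden source.
#' @param jitter_sd_ms SD of the copy lag noise (>= 0).
#' @param copy_p per-member copy probability.
#' @param seed optional seed; `NULL` inherits the current RNG stream.
#' @param ground_truth optional `ground_truth` to append to (one row per
#'   member pair).
#' @return list(spikes, ground_truth).
#' @export
inject_common_input <- function(spikes, trials, members, source_rate_hz,
                                jitter_sd_ms, copy_p, seed = NULL,
                                ground_truth = NULL) {
  if (length(members) < 2) stop("need at least 2 members")
  if (jitter_sd_ms < 0) stop("jitter_sd_ms must be non-negative")
  stopifnot(copy_p >= 0, copy_p <= 1, source_rate_hz >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ground_truth)) ground_truth <- empty_ground_truth()
  prs <- combn(sort(members), 2)
  for (i in seq_len(ncol(prs))) {
    ground_truth <- gt_add(ground_truth, "common_input", prs[1, i], prs[2, i],
                           0, copy_p, jitter_sd_ms, source_rate_hz)
  }
  if (copy_p > 0 && source_rate_hz > 0) {
    new <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      dur <- trials$duration_s[i]
      ns <- rpois(1, source_rate_hz * dur)
      if (ns == 0) next
      src <- runif(ns, 0, dur)
      got <- lapply(members, function(m) {
        take <- runif(ns) < copy_p
        if (!any(take)) return(NULL)
        tnew <- src[take] + rnorm(sum(take), 0, jitter_sd_ms / 1000)
        tnew <- tnew[tnew >= 0 & tnew <= dur]
        if (!length(tnew)) return(NULL)
        data.frame(unit_id = m, trial_id = trials$trial_id[i], time_s = tnew)
      })
      new[[i]] <- do.call(rbind, got)
    }
    new <- do.call(rbind, new)
    if (!is.null(new) && nrow(new)) {
      spikes <- rbind(spikes, new)
      spikes <- spikes[order(spikes$unit_id, spikes$trial_id, spikes$time_s), ]
      rownames(spikes) <- NULL
    }
  }
  list(spikes = spikes, ground_truth = ground_truth)
}

#' Generate a synthetic column with planted ground truth
#'
#' Samples background spikes by Bernoulli thinning of the per-trial rate
#' profiles on a 1 ms grid (with uniform sub-millisecond placement), applies
#' shared slow rate modulation per trial, then injects monosynaptic
#' connections and common-input groups.  Pair selection for planted
#' interactions favors nearby depths (exponential kernel) and similar
#' orientation preference, so distance and tuning relationships are present
#' by construction.  Deterministic for a fixed config seed.
#'
#' @param config a `column_config`.
#' @param seed optional override of `config$seed`.
#' @return list(spikes, trials, units, ground_truth).
#' @export
generate_column <- function(config, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_column_config(config)
  profiles <- make_rate_profiles(config)
  set.seed(child_seed(config$seed, "column"))
  U <- config$n_units
  dirs <- profiles$directions_deg
  Tn <- dim(profiles$rate)[3]
  tt <- (seq_len(Tn) - 0.5) / 1000

  depth <- sort(runif(U, config$depth_range_um[1], config$depth_range_um[2]),
                decreasing = TRUE)
  layer <- assign_layers(depth, anchor_um = 0,
                         thickness_table = config$thickness_table)

  n_trials <- config$n_directions * config$n_repeats
  cond <- sample(rep(dirs, config$n_repeats))
  trials <- data.frame(trial_id = seq_len(n_trials), direction_deg = cond,
                       spatial_freq_cpd = config$spatial_freq_cpd,
                       onset_s = (seq_len(n_trials) - 1) *
                         (config$trial_duration_s + 0.25),
                       duration_s = config$trial_duration_s)

  sm <- config$slow_mod
  spike_list <- vector("list", n_trials)
  expected <- numeric(U)
  for (i in seq_len(n_trials)) {
    d_idx <- match(trials$direction_deg[i], dirs)
    r <- profiles$rate[, d_idx, ]            # U x Tn, spikes/s
    if (sm$amplitude > 0) {
      phases <- runif(sm$n_groups, 0, 2 * pi)
      for (g in seq_len(sm$n_groups)) {
        fac <- 1 + sm$amplitude * sin(2 * pi * tt / sm$timescale_s + phases[g])
        sel <- profiles$slow_group == g
        if (any(sel)) r[sel, ] <- r[sel, , drop = FALSE] *
            rep(fac, each = sum(sel))
      }
    }
    p <- pmin(r / 1000, 1)
    expected <- expected + rowSums(p)
    fired <- which(matrix(runif(length(p)) < p, nrow = U), arr.ind = TRUE)
    if (nrow(fired)) {
      spike_list[[i]] <- data.frame(
        unit_id = fired[, 1],
        trial_id = i,
        time_s = (fired[, 2] - runif(nrow(fired))) / 1000)
    }
  }
  spikes <- do.call(rbind, spike_list)
  if (is.null(spikes)) {
    spikes <- data.frame(unit_id = integer(), trial_id = integer(),
                         time_s = numeric())
  }

  gt <- empty_ground_truth(data.frame(
    unit_id = seq_len(U), true_pref_deg = profiles$pref_deg,
    true_simple = profiles$simple,
    expected_rate_hz = expected / (n_trials * config$trial_duration_s)))

  cn <- config$connections
  pair_weight <- function(a, b) {
    w <- exp(-abs(depth[a] - depth[b]) / cn$distance_scale_um)
    if (isTRUE(cn$tuning_weight)) {
      w <- w * orientation_similarity(profiles$pref_deg[a],
                                      profiles$pref_deg[b])
    }
    w
  }
  n_want <- if (U >= 2) cn$n_monosynaptic + cn$n_common_input else 0L
  all_pairs <- if (U >= 2) combn(U, 2) else matrix(integer(), 2, 0)
  w <- if (ncol(all_pairs)) pair_weight(all_pairs[1, ], all_pairs[2, ]) else numeric()
  used <- logical(ncol(all_pairs))
  if (n_want > 0 && ncol(all_pairs) >= n_want && sum(w > 0) >= n_want) {
    chosen <- sample(ncol(all_pairs), n_want, prob = w)
    used[chosen] <- TRUE
    mono_idx <- chosen[seq_len(cn$n_monosynaptic)]
    ci_idx <- setdiff(chosen, mono_idx)
    # optional distance coupling: interaction strength halves every
    # efficacy_half_distance_um, and monosynaptic delay grows linearly with
    # depth distance (mono_delay_rate_ms_per_um); both off by default
    strength_factor <- function(d) {
      if (is.finite(cn$efficacy_half_distance_um)) {
        2^(-d / cn$efficacy_half_distance_um)
      } else 1
    }
    for (ix in mono_idx) {
      a <- all_pairs[1, ix]; b <- all_pairs[2, ix]
      if (runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
      d <- abs(depth[a] - depth[b])
      delay <- if (cn$mono_delay_rate_ms_per_um > 0) {
        min(0.5 + cn$mono_delay_rate_ms_per_um * d, 9)
      } else {
        runif(1, cn$mono_delay_range_ms[1], cn$mono_delay_range_ms[2])
      }
      res <- inject_monosynaptic(spikes, trials, a, b,
                                 cn$mono_efficacy_p * strength_factor(d),
                                 delay, cn$mono_jitter_sd_ms,
                                 ground_truth = gt)
      spikes <- res$spikes; gt <- res$ground_truth
    }
    for (ix in ci_idx) {
      members <- all_pairs[, ix]
      d <- abs(depth[members[1]] - depth[members[2]])
      res <- inject_common_input(spikes, trials, members, cn$ci_source_rate_hz,
                                 cn$ci_jitter_sd_ms,
                                 cn$ci_copy_p * strength_factor(d),
                                 ground_truth = gt)
      spikes <- res$spikes; gt <- res$ground_truth
    }
  } else if (n_want > 0) {
    warning("not enough eligible pairs to plant all requested connections")
  }

  counts <- tabulate(spikes$unit_id, nbins = U)
  units <- data.frame(unit_id = seq_len(U), depth_um = depth, layer = layer,
                      mean_rate_hz = counts /
                        (n_trials * config$trial_duration_s))
  spikes <- spikes[order(spikes$unit_id, spikes$trial_id, spikes$time_s), ]
  rownames(spikes) <- NULL
  list(spikes = spikes, trials = trials, units = units, ground_truth = gt)
}

#' Write ground truth to JSON
#' @param ground_truth a `ground_truth` object.
#' @param path output file.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(list(connections = ground_truth$connections,
                            units = ground_truth$units),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
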