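# Per-unit visual response statistics: trial responses, direction tuning
# curves, F1/F0 modulation ratio with simple/complex labeling, and pairwise
# orientation signal correlations.

#' Per-trial mean firing rates
#'
#' Mean rate (spikes/s) of every unit on every trial over the response window
#' `[latency_offset_s, duration_s]`, i.e. the stimulus period offset by a
#' fixed response latency.  Set `latency_offset_s = 0` to use the full
#' stimulus period (the convention for signal correlations).
#'
#' @param spikes,trials dataset tables.
#' @param unit_ids units to evaluate (default: all with spikes).
#' @param latency_offset_s response latency in seconds (default 0.030).
#' @return Data frame `unit_id, trial_id, rate_hz`, one row per unit x trial.
#' @export
trial_responses <- function(spikes, trials, unit_ids = NULL,
                            latency_offset_s = 0.030) {
  if (latency_offset_s >= min(trials$duration_s)) {
    stop("latency offset must be smaller than the trial duration")
  }
  if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
  dur <- trials$duration_s[match(spikes$trial_id, trials$trial_id)]
  keep <- spikes$time_s >= latency_offset_s & spikes$time_s <= dur
  sp <- spikes[keep, , drop = FALSE]
  grid <- expand.grid(unit_id = unit_ids, trial_id = trials$trial_id)
  cnt <- integer(nrow(grid))
  if (nrow(sp)) {
    key <- match(paste(sp$unit_id, sp$trial_id),
                 paste(grid$unit_id, grid$trial_id))
    tb <- tabulate(key, nbins = nrow(grid))
    cnt <- tb
  }
  win <- trials$duration_s[match(grid$trial_id, trials$trial_id)] -
    latency_offset_s
  data.frame(unit_id = grid$unit_id, trial_id = grid$trial_id,
             rate_hz = cnt / win)
}

#' Direction tuning curve and preferred direction
#'
#' Averages per-trial responses within each drift direction.  The preferred
#' direction is the argmax; ties are broken toward the smallest angle.
#'
#' @param responses data frame from [trial_responses()] for one unit or many
#'   (computed per unit).
#' @param trials dataset trial table.
#' @return A list of `tuning_profile` objects (one per unit), each with
#'   `unit_id`, `directions_deg`, `mean_response`, `preferred_direction_deg`.
#'   F1/F0 fields are filled by [modulation_ratio()].
#' @export
tuning_curve <- function(responses, trials) {
  dirs <- sort(unique(trials$direction_deg))
  resp_dir <- trials$direction_deg[match(responses$trial_id, trials$trial_id)]
  out <- lapply(split(seq_len(nrow(responses)), responses$unit_id),
                function(ix) {
    mr <- tapply(responses$rate_hz[ix], resp_dir[ix], mean)
    got <- as.numeric(names(mr))
    if (!setequal(got, dirs)) {
      stop("missing direction(s): ",
           paste(setdiff(dirs, got), collapse = ", "), call. = FALSE)
    }
    mr <- mr[match(dirs, got)]
    pref <- dirs[which.max(mr)]   # which.max takes the first = smallest angle
    structure(list(unit_id = responses$unit_id[ix[1]],
                   directions_deg = dirs,
                   mean_response = as.numeric(mr),
                   preferred_direction_deg = pref,
                   f0 = NA_real_, f1 = NA_real_,
                   modulation_ratio = NA_real_,
                   cell_class = NA_character_),
              class = "tuning_profile")
  })
  unname(out)
}

#' F1/F0 modulation ratio and simple/complex labeling
#'
#' Builds the pooled-repeat PSTH at the unit's preferred direction at 1 ms
#' resolution over the full stimulus period, then takes F0 as the mean rate
#' and F1 as the amplitude of the Fourier component at the grating temporal
#' frequency.  Units with modulation ratio F1/F0 strictly greater than 1 are
#' labeled simple, otherwise complex; zero-response units are flagged
#' `undefined` and excluded from class counts.
#'
#' @param spikes,trials dataset tables.
#' @param profile a `tuning_profile` from [tuning_curve()].
#' @param stimulus_tf_hz drift temporal frequency of the grating (Hz).
#' @return The completed `tuning_profile` with `f0`, `f1`,
#'   `modulation_ratio` and `cell_class` filled in.
#' @export
modulation_ratio <- function(spikes, trials, profile, stimulus_tf_hz) {
  stopifnot(inherits(profile, "tuning_profile"))
  tr <- trials[trials$direction_deg == profile$preferred_direction_deg, ,
               drop = FALSE]
  dur <- min(tr$duration_s)
  nb <- as.integer(round(dur * 1000))
  sp <- spikes[spikes$unit_id == profile$unit_id &
                 spikes$trial_id %in% tr$trial_id &
                 spikes$time_s < dur, , drop = FALSE]
  psth <- tabulate(pmin(nb, floor(sp$time_s * 1000) + 1L), nbins = nb) /
    (nrow(tr) * 0.001)                      # spikes/s per 1 ms bin
  tt <- (seq_len(nb) - 0.5) / 1000
  f0 <- mean(psth)
  f1 <- 2 * Mod(mean(psth * exp(-2i * pi * stimulus_tf_hz * tt)))
  profile$f0 <- f0
  profile$f1 <- f1
  if (f0 <= 0) {
    profile$modulation_ratio <- NA_real_
    profile$cell_class <- "undefined"
  } else {
    profile$modulation_ratio <- f1 / f0
    profile$cell_class <- classify_modulation_ratio(f1 / f0)
  }
  profile
}

#' Simple/complex rule on the modulation ratio
#'
#' Simple iff F1/F0 is strictly greater than 1; a ratio of exactly 1 is
#' complex.  `NA` maps to `"undefined"`.
#'
#' @param ratio numeric modulation ratio(s).
#' @return Character vector of `"simple"`, `"complex"`, or `"undefined"`.
#' @export
classify_modulation_ratio <- function(ratio) {
  out <- ifelse(is.na(ratio), "undefined",
                ifelse(ratio > 1, "simple", "complex"))
  as.character(out)
}

#' Compute completed tuning profiles for all units
#'
#' Convenience wrapper: per-trial responses (30 ms latency), tuning curves,
#' and modulation ratios for every unit.
#'
#' @inheritParams trial_responses
#' @param stimulus_tf_hz grating temporal frequency (Hz); default taken from
#'   the most common `spatial_freq_cpd`-independent convention is not
#'   possible, so it must be supplied.
#' @return List of completed `tuning_profile` objects.
#' @export
compute_tuning <- function(spikes, trials, stimulus_tf_hz, unit_ids = NULL,
                           latency_offset_s = 0.030) {
  resp <- trial_responses(spikes, trials, unit_ids, latency_offset_s)
  profs <- tuning_curve(resp, trials)
  lapply(profs, function(p) modulation_ratio(spikes, trials, p,
                                             stimulus_tf_hz))
}

#' Flatten tuning profiles to a table
#' @param profiles list of `tuning_profile` objects.
#' @return Data frame `unit_id, preferred_direction_deg, f0, f1,
#'   modulation_ratio, cell_class`.
#' @export
tuning_table <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) data.frame(
    unit_id = p$unit_id,
    preferred_direction_deg = p$preferred_direction_deg,
    f0 = p$f0, f1 = p$f1, modulation_ratio = p$modulation_ratio,
    cell_class = p$cell_class)))
}

#' Orientation signal correlation between two units
#'
#' Pearson correlation of the two units' mean responses across the stimulus
#' directions.  For signal correlations the mean responses are conventionally
#' computed over the full stimulus period (no latency offset).
#'
#' @param profile_j,profile_k `tuning_profile` objects on the same direction
#'   grid.
#' @return list(unit_pair, r_ori); `r_ori` is `NA` (pair flagged) when either
#'   tuning vector has zero variance.
#' @export
signal_correlation <- function(profile_j, profile_k) {
  stopifnot(identical(profile_j$directions_deg, profile_k$directions_deg))
  a <- profile_j$mean_response
  b <- profile_k$mean_response
  r <- if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  list(unit_pair = c(profile_j$unit_id, profile_k$unit_id), r_ori = r)
}

#' Pairwise signal correlation matrix
#'
#' @param profiles list of `tuning_profile` objects (typically computed with
#'   `latency_offset_s = 0` responses).
#' @return Symmetric matrix of r_ori with unit ids as dimnames.
#' @export
signal_correlation_matrix <- function(profiles) {
  mat <- do.call(cbind, lapply(profiles, function(p) p$mean_response))
  ids <- vapply(profiles, function(p) p$unit_id, numeric(1))
  zero <- apply(mat, 2, sd) == 0
  r <- suppressWarnings(cor(mat))
  r[zero, ] <- NA_real_
  r[, zero] <- NA_real_
  dimnames(r) <- list(ids, ids)
  r
}
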