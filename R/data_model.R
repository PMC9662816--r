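# Domain tables, CSV readers/writers, binning, and inclusion filters.
#
# Conventions used throughout the package:
#   * spike times are seconds relative to trial onset,
#   * bins are half-open [t, t + delta),
#   * lambda is spikes per *bin* (dimensionless CCGs, efficacy in
#     coincidences per spike),
#   * depth is micrometers, signed, 0 at the layer 4c/5 border
#     (negative = deeper).

LAYER_LEVELS <- c("2/3", "4A/B", "4c_alpha", "4c_beta", "5", "6", "unknown")

schema_error <- function(file, row, msg) {
  stop(sprintf("schema error in %s%s: %s", file,
               if (is.null(row)) "" else sprintf(" (row %d)", row), msg),
       call. = FALSE)
}

check_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    schema_error(file, NULL, paste("missing column(s):",
                                   paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) return(invisible(df))
  for (cl in cols) {
    if (!is.numeric(df[[cl]]) && cl != "layer") {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cl]]))))[1]
      schema_error(file, bad, sprintf("non-numeric values in '%s'", cl))
    }
  }
  invisible(df)
}

validate_trials <- function(trials, file = "trials") {
  check_columns(trials, c("trial_id", "direction_deg", "spatial_freq_cpd",
                          "onset_s", "duration_s"), file)
  if (anyDuplicated(trials$trial_id)) {
    schema_error(file, NULL, "duplicate trial_id")
  }
  if (any(trials$direction_deg < 0 | trials$direction_deg >= 360)) {
    schema_error(file, NULL, "direction_deg must be in [0, 360)")
  }
  if (any(trials$duration_s <= 0)) {
    schema_error(file, NULL, "duration_s must be positive")
  }
  trials
}

validate_units <- function(units, file = "units") {
  check_columns(units, c("unit_id", "depth_um", "layer"), file)
  if (anyDuplicated(units$unit_id)) schema_error(file, NULL, "duplicate unit_id")
  units$layer <- as.character(units$layer)
  bad <- which(!units$layer %in% LAYER_LEVELS)[1]
  if (!is.na(bad)) {
    schema_error(file, bad, sprintf("unknown layer label '%s'", units$layer[bad]))
  }
  units
}

validate_spikes <- function(spikes, trials, units, file = "spikes") {
  check_columns(spikes, c("unit_id", "trial_id", "time_s"), file)
  bad <- which(!spikes$unit_id %in% units$unit_id)[1]
  if (!is.na(bad)) {
    schema_error(file, bad, sprintf("unknown unit_id %s", spikes$unit_id[bad]))
  }
  bad <- which(!spikes$trial_id %in% trials$trial_id)[1]
  if (!is.na(bad)) {
    schema_error(file, bad, sprintf("unknown trial_id %s", spikes$trial_id[bad]))
  }
  dur <- trials$duration_s[match(spikes$trial_id, trials$trial_id)]
  bad <- which(spikes$time_s < 0 | spikes$time_s > dur)[1]
  if (!is.na(bad)) schema_error(file, bad, "time_s outside [0, duration_s]")
  spikes
}

#' Load a spike dataset from its three CSV files
#'
#' Reads and cross-validates the spike, trial, and unit tables.  Column
#' schemas: `spikes.csv` has `unit_id, trial_id, time_s` (seconds relative to
#' trial onset); `trials.csv` has `trial_id, direction_deg, spatial_freq_cpd,
#' onset_s, duration_s`; `units.csv` has `unit_id, depth_um, layer`
#' (`mean_rate_hz` optional, recomputed downstream).
#'
#' @param spike_path,trial_path,unit_path paths to the three CSV files.
#' @param verbose log row counts via `message()`.
#' @return A list with elements `spikes`, `trials`, `units` (data frames).
#' @export
load_dataset <- function(spike_path, trial_path, unit_path, verbose = TRUE) {
  for (p in c(spike_path, trial_path, unit_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  trials <- validate_trials(read.csv(trial_path), trial_path)
  units <- validate_units(read.csv(unit_path), unit_path)
  spikes <- validate_spikes(read.csv(spike_path), trials, units, spike_path)
  if (verbose) {
    message(sprintf("loaded %d spikes, %d trials, %d units",
                    nrow(spikes), nrow(trials), nrow(units)))
  }
  list(spikes = spikes, trials = trials, units = units)
}

#' Write a spike dataset to three CSV files
#'
#' Inverse of [load_dataset()]; the round trip preserves every record.
#'
#' @param dataset list with `spikes`, `trials`, `units` data frames.
#' @param dir output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("spikes.csv", "trials.csv", "units.csv"))
  # 17 significant digits so doubles survive the text round trip bit-exactly
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) format(col, digits = 17, trim = TRUE,
                                 scientific = FALSE) else col
    })
    df
  }
  write.csv(fmt(dataset$spikes), paths[1], row.names = FALSE, quote = FALSE)
  write.csv(fmt(dataset$trials), paths[2], row.names = FALSE, quote = FALSE)
  write.csv(fmt(dataset$units), paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Bin spike trains into trial-by-bin binary arrays
#'
#' Discretizes spikes into half-open bins `[t, t + delta)` within an analysis
#' window common to all trials, producing the binary arrays that all
#' correlogram computations operate on.  Multiple spikes in one bin are
#' clipped to 1 (binary convention); the number of clipped spikes is recorded
#' per unit.  The per-unit mean rate `lambda` is in spikes per bin, computed
#' over exactly the binned window.
#'
#' @param spikes,trials,units data frames as returned by [load_dataset()].
#' @param window numeric length-2, analysis window `(t0, t1)` in seconds
#'   relative to trial onset (default `c(0.4, 1)`, skipping the onset
#'   transient).
#' @param bin_width_s bin width in seconds (default 0.001).
#' @return A `binned_spikes` object: list with `x` (unit x trial x bin 0/1
#'   array), `unit_ids`, `trial_ids`, `window`, `bin_width_s`, `M` trials,
#'   `N` bins, `lambda` (spikes/bin per unit), `clipped` (spikes lost to the
#'   binary convention per unit).
#' @export
bin_spikes <- function(spikes, trials, units, window = c(0.4, 1),
                       bin_width_s = 0.001) {
  if (bin_width_s <= 0) stop("bin_width_s must be positive", call. = FALSE)
  if (length(window) != 2 || window[2] <= window[1]) {
    stop("window must be an increasing (t0, t1) pair", call. = FALSE)
  }
  if (window[1] < 0 || window[2] > min(trials$duration_s) + 1e-12) {
    stop("analysis window outside trial duration", call. = FALSE)
  }
  N <- as.integer(round((window[2] - window[1]) / bin_width_s))
  if (abs(N * bin_width_s - (window[2] - window[1])) > bin_width_s) {
    stop("bin_width_s does not divide the window length", call. = FALSE)
  }
  unit_ids <- sort(unique(units$unit_id))
  trial_ids <- sort(unique(trials$trial_id))
  M <- length(trial_ids)
  U <- length(unit_ids)
  x <- array(0L, dim = c(U, M, N))
  clipped <- setNames(integer(U), unit_ids)
  inw <- spikes$time_s >= window[1] & spikes$time_s < window[2]
  sp <- spikes[inw, , drop = FALSE]
  if (nrow(sp)) {
    u <- match(sp$unit_id, unit_ids)
    tr <- match(sp$trial_id, trial_ids)
    # guard against representation error at exact bin boundaries
    b <- pmin(N, floor((sp$time_s - window[1]) / bin_width_s + 1e-9) + 1L)
    idx <- (b - 1L) * (U * M) + (tr - 1L) * U + u
    cnt <- table(idx)
    pos <- as.integer(names(cnt))
    x[pos] <- 1L
    over <- as.integer(cnt) - 1L
    if (any(over > 0L)) {
      uu <- ((pos - 1L) %% (U * M)) %% U + 1L
      cl <- tapply(over, uu, sum)
      clipped[as.integer(names(cl))] <- as.integer(cl)
    }
  }
  lambda <- apply(x, 1, mean)
  structure(list(x = x, unit_ids = unit_ids, trial_ids = trial_ids,
                 window = window, bin_width_s = bin_width_s,
                 M = M, N = N, lambda = setNames(lambda, unit_ids),
                 clipped = clipped),
            class = "binned_spikes")
}

#' @export
print.binned_spikes <- function(x, ...) {
  cat(sprintf("binned_spikes: %d units x %d trials x %d bins (%g ms bins, window %g-%g s)\n",
              length(x$unit_ids), x$M, x$N, x$bin_width_s * 1000,
              x$window[1], x$window[2]))
  cat(sprintf("  mean rate %.2f spikes/s, %d spikes clipped to binary bins\n",
              mean(x$lambda) / x$bin_width_s, sum(x$clipped)))
  invisible(x)
}

#' Drop units below a minimum firing rate
#'
#' Applies the inclusion criterion of a minimum firing rate, computed from
#' `lambda` over the analysis window.  The bound is inclusive: a unit at
#' exactly `min_rate_hz` is retained.
#'
#' @param binned a `binned_spikes` object.
#' @param min_rate_hz inclusion threshold in spikes/s (default 3).
#' @param verbose log removed units.
#' @return A `binned_spikes` object restricted to the retained units.
#' @export
filter_units_by_rate <- function(binned, min_rate_hz = 3, verbose = TRUE) {
  stopifnot(inherits(binned, "binned_spikes"))
  rate_hz <- binned$lambda / binned$bin_width_s
  keep <- rate_hz >= min_rate_hz - 1e-12
  if (!any(keep)) {
    warning("all units fall below the rate criterion; returning empty result")
  }
  if (verbose && any(!keep)) {
    message(sprintf("rate filter removed %d unit(s): %s", sum(!keep),
                    paste(binned$unit_ids[!keep], collapse = ", ")))
  }
  out <- binned
  out$x <- binned$x[keep, , , drop = FALSE]
  out$unit_ids <- binned$unit_ids[keep]
  out$lambda <- binned$lambda[keep]
  out$clipped <- binned$clipped[keep]
  out
}
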