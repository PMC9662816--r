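# End-to-end orchestration: simulate (or load) -> bin -> tune -> correlate
# -> classify -> summarize, driven by a single config, with a structured
# JSON report.

#' Pipeline configuration
#'
#' All thresholds default to the analysis conventions used throughout the
#' package: 0.4-1 s analysis window, 1 ms bins, 25 ms jitter window, 7 SD
#' significance with a 10 ms lag window, 3 spikes/s inclusion, 50 um /
#' 0.167 ms / 20% double-count screen, 86-310 um logistic-regression band,
#' and a 5 ms monosynaptic width criterion.  Every stochastic stage has an
#' explicit seed.
#'
#' @param simulate generate a synthetic column (`TRUE`) or load CSVs from
#'   `paths`.
#' @param column a [column_config()] for the simulator.
#' @param paths list(spikes, trials, units) of input CSVs when
#'   `simulate = FALSE`.
#' @param window,bin_width_s analysis window (s) and bin width (s).
#' @param min_rate_hz unit inclusion threshold.
#' @param jitter a [jitter_config()].
#' @param threshold_sd,max_peak_lag_ms CCG significance parameters.
#' @param double_count list(dist_um, coincidence_ms, frac, exclude).
#' @param clustering list(k_range, replicates, max_iter, perplexity,
#'   tsne_iter, fwhm_threshold_ms, tol, min_rows).
#' @param stats list(n_bins, distance_range, monosyn_width_ms).
#' @param seeds list of integer seeds per stochastic stage (embed, kmeans,
#'   ordering, bootstrap).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, column = column_config(),
                            paths = NULL, window = c(0.4, 1),
                            bin_width_s = 0.001, min_rate_hz = 3,
                            jitter = jitter_config(),
                            threshold_sd = 7, max_peak_lag_ms = 10,
                            double_count = list(dist_um = 50,
                                                coincidence_ms = 0.167,
                                                frac = 0.20, exclude = TRUE),
                            clustering = list(k_range = 1:10,
                                              replicates = 50, max_iter = 100,
                                              perplexity = 30,
                                              tsne_iter = 1000,
                                              fwhm_threshold_ms = 4,
                                              tol = 0.02, min_rows = 40),
                            stats = list(n_bins = 10,
                                         distance_range = c(86, 310),
                                         monosyn_width_ms = 5),
                            seeds = list(embed = 1L, kmeans = 1L,
                                         ordering = 1L, bootstrap = 1L)) {
  if (!simulate && (is.null(paths) || !all(c("spikes", "trials", "units")
                                           %in% names(paths)))) {
    stop("simulation disabled but input paths are missing", call. = FALSE)
  }
  structure(list(simulate = simulate, column = column, paths = paths,
                 window = window, bin_width_s = bin_width_s,
                 min_rate_hz = min_rate_hz, jitter = jitter,
                 threshold_sd = threshold_sd,
                 max_peak_lag_ms = max_peak_lag_ms,
                 double_count = double_count, clustering = clustering,
                 stats = stats, seeds = seeds),
            class = "pipeline_config")
}

#' Write a pipeline configuration to JSON
#' @param config a [pipeline_config()].
#' @param path output file.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, strip)
      attributes(x) <- list(names = names(x))
    } else if (!is.null(names(x))) {
      x <- as.list(x)                      # keep names (e.g. thickness table)
    }
    x
  }
  jsonlite::write_json(strip(unclass(config)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' Inverse of [write_pipeline_config()]; reconstructs the typed config so a
#' written config round-trips losslessly.
#'
#' @param path JSON file written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  col <- raw$column
  col$thickness_table <- unlist(col$thickness_table)
  col$base_rate <- as.list(col$base_rate)
  col$tuning <- as.list(col$tuning)
  col$onset_transient <- as.list(col$onset_transient)
  col$slow_mod <- as.list(col$slow_mod)
  col$connections <- lapply(as.list(col$connections), function(v) {
    if (is.character(v)) as.numeric(v) else v   # "Inf" back to Inf
  })
  column <- do.call(column_config, col)
  jit <- do.call(jitter_config, as.list(raw$jitter))
  pipeline_config(simulate = raw$simulate, column = column,
                  paths = raw$paths, window = raw$window,
                  bin_width_s = raw$bin_width_s,
                  min_rate_hz = raw$min_rate_hz, jitter = jit,
                  threshold_sd = raw$threshold_sd,
                  max_peak_lag_ms = raw$max_peak_lag_ms,
                  double_count = as.list(raw$double_count),
                  clustering = as.list(raw$clustering),
                  stats = as.list(raw$stats),
                  seeds = as.list(raw$seeds))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a simulated or loaded dataset and returns a
#' report bundle; with `out_dir` set, also writes the dataset CSVs, the
#' per-pair table, tuning table, class tables, and `report.json`.
#' Deterministic for a fixed config.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @param verbose log stage progress.
#' @return A list: `dataset`, `binned`, `tuning`, `ccg_set`, `classes`
#'   (clustering results or NULL), `stats`, `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  dataset <- stage("input", {
    if (config$simulate) {
      say("simulating column (%d units, seed %d)", config$column$n_units,
          config$column$seed)
      generate_column(config$column)
    } else {
      load_dataset(config$paths$spikes, config$paths$trials,
                   config$paths$units, verbose = verbose)
    }
  })

  binned <- stage("binning", {
    b <- bin_spikes(dataset$spikes, dataset$trials, dataset$units,
                    window = config$window,
                    bin_width_s = config$bin_width_s)
    filter_units_by_rate(b, config$min_rate_hz, verbose = verbose)
  })
  say("binned %d units pass the %g spikes/s filter", length(binned$unit_ids),
      config$min_rate_hz)

  # drift temporal frequency: from the simulator config, else a 4 Hz default
  tf <- if (config$simulate) config$column$stimulus_tf_hz else 4
  tuning <- stage("tuning", {
    profs <- compute_tuning(dataset$spikes, dataset$trials, tf,
                            unit_ids = binned$unit_ids)
    profs_full <- compute_tuning(dataset$spikes, dataset$trials, tf,
                                 unit_ids = binned$unit_ids,
                                 latency_offset_s = 0)
    list(profiles = profs, table = tuning_table(profs),
         r_ori = signal_correlation_matrix(profs_full))
  })

  dbl <- stage("double_count_screen", {
    screen_double_counts(dataset$spikes,
                         dataset$units[dataset$units$unit_id %in%
                                         binned$unit_ids, , drop = FALSE],
                         dist_um = config$double_count$dist_um,
                         coincidence_ms = config$double_count$coincidence_ms,
                         frac = config$double_count$frac)
  })

  ccg_set <- stage("correlograms", {
    compute_all_pairs(binned, dataset$units, jitter = config$jitter,
                      threshold_sd = config$threshold_sd,
                      max_peak_lag_ms = config$max_peak_lag_ms,
                      double_flags = dbl,
                      exclude_flagged = isTRUE(config$double_count$exclude))
  })
  say("%d/%d pairs significant", sum(ccg_set$pairs$significant),
      nrow(ccg_set$pairs))

  # attach tuning annotations to the pair table
  pairs <- ccg_set$pairs
  tt <- tuning$table
  pairs$r_ori <- mapply(function(a, b) {
    tuning$r_ori[as.character(a), as.character(b)]
  }, pairs$ref, pairs$target)
  pairs$cell_class_ref <- tt$cell_class[match(pairs$ref, tt$unit_id)]
  pairs$cell_class_target <- tt$cell_class[match(pairs$target, tt$unit_id)]

  classes <- NULL
  n_sig <- sum(pairs$significant)
  if (2 * n_sig >= config$clustering$min_rows) {
    classes <- stage("classification", {
      feats <- normalize_ccgs(ccg_set)
      emb <- embed_ccgs(feats, perplexity = config$clustering$perplexity,
                        max_iter = config$clustering$tsne_iter,
                        seed = config$seeds$embed)
      fits <- cluster_kmeans(emb, k_range = config$clustering$k_range,
                             replicates = config$clustering$replicates,
                             max_iter = config$clustering$max_iter,
                             seed = config$seeds$kmeans)
      ev <- evaluate_clusterings(emb, fits)
      k <- select_k(ev, tol = config$clustering$tol)
      labels <- fits[[as.character(k)]]$labels
      tpl <- class_templates(feats, labels,
                             fwhm_threshold_ms =
                               config$clustering$fwhm_threshold_ms)
      asg <- assign_pair_classes(feats, labels, tpl,
                                 seed = config$seeds$ordering)
      list(features = feats, embedding = emb, evaluation = ev, k = k,
           labels = labels, templates = tpl, assignment = asg)
    })
    asg <- classes$assignment
    # orient pair rows to the randomly chosen reference ordering
    flip <- asg$ref != pairs$ref[asg$pair_index]
    pairs$class_label <- NA_character_
    pairs$class_label[asg$pair_index] <- asg$class_label
    pairs$class_ref <- pairs$ref
    pairs$class_target <- pairs$target
    pairs$class_ref[asg$pair_index] <- asg$ref
    pairs$class_target[asg$pair_index] <- asg$target
    ix <- asg$pair_index[flip]
    pairs$peak_lag_ms[ix] <- -pairs$peak_lag_ms[ix]
    tmp <- pairs$cell_class_ref[ix]
    pairs$cell_class_ref[ix] <- pairs$cell_class_target[ix]
    pairs$cell_class_target[ix] <- tmp
    tmp <- pairs$layer_ref[ix]
    pairs$layer_ref[ix] <- pairs$layer_target[ix]
    pairs$layer_target[ix] <- tmp
    pairs$ref[ix] <- pairs$class_ref[ix]
    pairs$target[ix] <- pairs$class_target[ix]
  } else {
    say("too few significant pairs (%d) for shape clustering", n_sig)
  }

  sig <- pairs[pairs$significant & !is.na(pairs$r_ori), , drop = FALSE]
  stats_out <- stage("statistics", {
    out <- list()
    if (nrow(sig) >= config$stats$n_bins) {
      out$lag_vs_distance <- binned_relationship(
        sig$distance_um, abs(sig$peak_lag_ms), config$stats$n_bins, "mean",
        seed = config$seeds$bootstrap)
      out$eff_vs_distance <- binned_relationship(
        sig$distance_um, sig$peak_efficacy, config$stats$n_bins, "median",
        seed = config$seeds$bootstrap)
      out$lag_linear <- fit_linear(sig$distance_um, abs(sig$peak_lag_ms),
                                   "MSE")
      med <- out$eff_vs_distance
      if (all(med$stat > 0)) {
        out$eff_exponential <- fit_exponential_decay(med$bin_center, med$stat)
      }
      out$reg_lag <- fit_standardized_regression(sig, "peak_lag")
      out$reg_eff <- fit_standardized_regression(sig, "peak_efficacy")
      out$matching <- distance_match(sig)
    }
    if (!is.null(classes) && sum(!is.na(sig$class_label)) >= 10) {
      out$composition <- class_composition_tests(sig)
      out$direction <- simple_complex_direction_test(sig)
    }
    out
  })

  report <- list(
    n_units = length(binned$unit_ids),
    n_trials = binned$M,
    n_pairs = nrow(pairs),
    n_significant = sum(pairs$significant),
    n_significant_troughs = sum(pairs$significant_trough),
    n_flagged_double = sum(pairs$flagged_double),
    mean_r_ori_all = mean(pairs$r_ori, na.rm = TRUE),
    mean_r_ori_significant = mean(sig$r_ori, na.rm = TRUE),
    selected_k = if (!is.null(classes)) classes$k,
    class_counts = if (!is.null(classes))
      as.list(table(pairs$class_label[pairs$significant])),
    fits = list(
      lag_linear = stats_out$lag_linear,
      eff_exponential = stats_out$eff_exponential,
      reg_lag = stats_out$reg_lag,
      reg_eff = stats_out$reg_eff),
    direction_test = stats_out$direction)

  result <- list(dataset = dataset, binned = binned, tuning = tuning,
                 double_flags = dbl, ccg_set = ccg_set, pairs = pairs,
                 classes = classes, stats = stats_out, report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_dataset(dataset[c("spikes", "trials", "units")], out_dir)
    if (!is.null(dataset$ground_truth)) {
      write_ground_truth(dataset$ground_truth,
                         file.path(out_dir, "ground_truth.json"))
    }
    write.csv(pairs, file.path(out_dir, "ccg_pairs.csv"), row.names = FALSE)
    write.csv(tuning$table, file.path(out_dir, "tuning.csv"),
              row.names = FALSE)
    if (!is.null(classes)) {
      write.csv(classes$evaluation, file.path(out_dir, "evaluation.csv"),
                row.names = FALSE)
      tplm <- classes$templates
      write.csv(data.frame(class = rep(tplm$class_label,
                                       each = length(tplm$lags_ms)),
                           cluster = rep(tplm$cluster,
                                         each = length(tplm$lags_ms)),
                           lag_ms = rep(tplm$lags_ms, length(tplm$cluster)),
                           value = as.numeric(t(tplm$templates))),
                file.path(out_dir, "templates.csv"), row.names = FALSE)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  result
}
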