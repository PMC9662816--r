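# Shape-based classification of significant CCGs: z-scored 21-lag features,
# t-SNE embedding, k-means with elbow (explained variance) and silhouette
# model selection, semantic template labeling, and the narrow-peak
# monosynaptic-candidate rule.

CCG_CLASS_LEVELS <- c("S_sync", "B_sync", "F_async", "R_async", "unclassified")

#' Build the z-scored CCG feature matrix
#'
#' Restricts each significant corrected CCG to lags -10..+10 ms (21
#' features), includes both pair orderings (the reversed ordering is the
#' lag-mirrored curve, avoiding directional bias in the templates), and
#' z-scores each row so clustering reflects shape rather than magnitude.
#'
#' @param ccg_set a `ccg_set` from [compute_all_pairs()] with curves kept.
#' @param feature_lag_ms half-width of the feature window (default 10).
#' @param significant_only use only significant pairs (default TRUE).
#' @return A `ccg_features` list: `x` (rows x 21 matrix), `ref`, `target`,
#'   `pair_index` (row of `ccg_set$pairs`), `lags_ms`.  Zero-variance rows
#'   are dropped with a warning.
#' @export
normalize_ccgs <- function(ccg_set, feature_lag_ms = 10,
                           significant_only = TRUE) {
  stopifnot(inherits(ccg_set, "ccg_set"), !is.null(ccg_set$corrected))
  sel <- if (significant_only) which(ccg_set$pairs$significant)
         else seq_len(nrow(ccg_set$pairs))
  if (length(sel) < 1) stop("no significant CCGs to classify", call. = FALSE)
  keep_lags <- abs(ccg_set$lags_ms) <= feature_lag_ms
  fwd <- ccg_set$corrected[sel, keep_lags, drop = FALSE]
  rev_ <- fwd[, rev(seq_len(ncol(fwd))), drop = FALSE]
  x <- rbind(fwd, rev_)
  ref <- c(ccg_set$pairs$ref[sel], ccg_set$pairs$target[sel])
  target <- c(ccg_set$pairs$target[sel], ccg_set$pairs$ref[sel])
  pair_index <- c(sel, sel)
  sds <- apply(x, 1, sd)
  ok <- sds > 0
  if (any(!ok)) {
    warning(sum(!ok), " zero-variance CCG row(s) dropped")
    x <- x[ok, , drop = FALSE]
    ref <- ref[ok]; target <- target[ok]; pair_index <- pair_index[ok]
  }
  x <- t(scale(t(x)))
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  structure(list(x = x, ref = ref, target = target, pair_index = pair_index,
                 lags_ms = ccg_set$lags_ms[keep_lags]),
            class = "ccg_features")
}

#' Embed CCG features with t-SNE
#'
#' Reduces the 21-lag feature rows to `out_dims` dimensions with
#' t-distributed stochastic neighbor embedding.  The embedding is seeded and
#' deterministic; its contract is cluster recoverability, not particular
#' coordinates.  Perplexity is clamped to `(n - 1) / 3` for small inputs.
#'
#' @param features a `ccg_features` object or a numeric matrix.
#' @param out_dims embedding dimensionality (default 3).
#' @param perplexity t-SNE perplexity (default 30).
#' @param max_iter gradient-descent iterations (default 1000).
#' @param seed RNG seed.
#' @return Numeric matrix (rows x out_dims).
#' @export
embed_ccgs <- function(features, out_dims = 3, perplexity = 30,
                       max_iter = 1000, seed = 1L) {
  x <- if (inherits(features, "ccg_features")) features$x else features
  n <- nrow(x)
  if (n < out_dims + 1) stop("too few rows to embed", call. = FALSE)
  if (all(apply(x, 2, function(cl) length(unique(cl)) == 1L))) {
    stop("degenerate input: all rows identical", call. = FALSE)
  }
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 1) stop("too few rows for any valid perplexity")
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = out_dims, perplexity = perplexity,
                      max_iter = max_iter, check_duplicates = FALSE,
                      pca = FALSE, verbose = FALSE)
  fit$Y
}

#' K-means over a range of cluster counts
#'
#' Best-of-replicates k-means (lowest within-cluster sum of squares) for each
#' k, seeded.
#'
#' @param embedding numeric matrix of points.
#' @param k_range candidate cluster counts (default 1:10).
#' @param replicates random restarts per k (default 50).
#' @param max_iter Lloyd iterations (default 100).
#' @param seed RNG seed.
#' @return List keyed by k (as character) with elements `labels`, `centers`,
#'   `wcss`; k values exceeding the row count are skipped with a warning.
#' @export
cluster_kmeans <- function(embedding, k_range = 1:10, replicates = 50,
                           max_iter = 100, seed = 1L) {
  embedding <- as.matrix(embedding)
  out <- list()
  set.seed(seed)
  for (k in k_range) {
    if (k > nrow(embedding)) {
      warning("k = ", k, " exceeds the number of points; skipped")
      next
    }
    fit <- suppressWarnings(
      kmeans(embedding, centers = k, nstart = replicates,
             iter.max = max_iter))
    out[[as.character(k)]] <- list(labels = fit$cluster,
                                   centers = fit$centers,
                                   wcss = fit$tot.withinss)
  }
  out
}

#' Fraction of variance explained by a clustering
#'
#' eta_k = (TSS - WCSS_k) / TSS with squared Euclidean norms, the standard
#' variance decomposition (eta_1 = 0; eta = 1 for zero within-cluster
#' scatter).
#'
#' @param points numeric matrix.
#' @param labels cluster assignment covering all points.
#' @return list(k, eta, tss, wcss).
#' @export
explained_variance <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(length(labels) == nrow(points))
  if (any(table(labels) == 0)) stop("empty cluster", call. = FALSE)
  ctr <- colMeans(points)
  tss <- sum(sweep(points, 2, ctr)^2)
  wcss <- sum(vapply(split(seq_len(nrow(points)), labels), function(ix) {
    sub <- points[ix, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
  list(k = length(unique(labels)), eta = if (tss > 0) (tss - wcss) / tss else 0,
       tss = tss, wcss = wcss)
}

#' Mean silhouette score of a clustering
#'
#' Standard silhouette with Euclidean distances: for each point,
#' `(b - a) / max(a, b)` where `a` is the mean distance to its own cluster
#' and `b` the smallest mean distance to another cluster; singleton clusters
#' score 0.  Undefined for k = 1 or all-identical points (returns `NA`).
#'
#' @param points numeric matrix.
#' @param labels cluster assignment.
#' @return Mean silhouette (numeric scalar).
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  labs <- unique(labels)
  if (length(labs) < 2 || length(labs) >= n) return(NA_real_)
  d <- as.matrix(dist(points))
  if (max(d) == 0) return(NA_real_)
  s <- numeric(n)
  sizes <- table(labels)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    ni <- sizes[[as.character(labels[i])]]
    if (ni == 1L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (ni - 1)
    b <- min(vapply(labs[labs != labels[i]], function(l) {
      mean(d[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Evaluate a k-means sweep
#'
#' @param embedding points used for clustering.
#' @param fits result of [cluster_kmeans()].
#' @return Data frame `k, eta, silhouette, wcss`.
#' @export
evaluate_clusterings <- function(embedding, fits) {
  do.call(rbind, lapply(fits, function(f) {
    k <- length(unique(f$labels))
    data.frame(k = k,
               eta = explained_variance(embedding, f$labels)$eta,
               silhouette = silhouette_score(embedding, f$labels),
               wcss = f$wcss)
  }))
}

#' Select the number of clusters
#'
#' Among the k whose silhouette is within `tol` of the maximum, picks the one
#' with the largest explained variance eta_k - i.e. silhouette proposes a
#' plateau and the elbow criterion breaks the tie toward more explained
#' variance.
#'
#' @param evaluation data frame from [evaluate_clusterings()] (columns `k`,
#'   `eta`, `silhouette`).
#' @param tol silhouette tolerance (default 0.02).
#' @return The selected k (integer).
#' @export
select_k <- function(evaluation, tol = 0.02) {
  ev <- evaluation[!is.na(evaluation$silhouette), , drop = FALSE]
  stopifnot(nrow(ev) >= 1)
  near <- ev[ev$silhouette >= max(ev$silhouette) - tol, , drop = FALSE]
  near$k[which.max(near$eta)]
}

#' Cluster templates and semantic class labels
#'
#' The template of each cluster is the mean z-scored curve.  Labeling rule:
#' a template whose peak lies within +-1 ms of zero is synchronous, split
#' into sharp (`S_sync`) versus broad (`B_sync`) by full width at half
#' maximum against `fwhm_threshold_ms`; a peak later than +1 ms is `F_async`
#' (reference leads), earlier than -1 ms is `R_async`.  Flat templates are
#' labeled `unclassified`.
#'
#' @param features a `ccg_features` object (or matrix of z-scored rows).
#' @param labels cluster labels, one per feature row.
#' @param lags_ms lag axis of the feature columns.
#' @param fwhm_threshold_ms sharp/broad boundary (default 4 ms).
#' @return A `ccg_templates` list: `templates` (k x lags matrix),
#'   `class_label` per cluster, `fwhm_ms`, `peak_lag_ms`.
#' @export
class_templates <- function(features, labels, lags_ms = NULL,
                            fwhm_threshold_ms = 4) {
  x <- if (inherits(features, "ccg_features")) features$x else as.matrix(features)
  if (is.null(lags_ms)) {
    lags_ms <- if (inherits(features, "ccg_features")) features$lags_ms
               else seq(-10, 10)
  }
  stopifnot(length(labels) == nrow(x), length(lags_ms) == ncol(x))
  ks <- sort(unique(labels))
  templates <- t(vapply(ks, function(k) colMeans(x[labels == k, , drop = FALSE]),
                        numeric(ncol(x))))
  rownames(templates) <- ks
  peak_lag <- numeric(length(ks))
  fwhm <- numeric(length(ks))
  cls <- character(length(ks))
  for (i in seq_along(ks)) {
    tpl <- templates[i, ]
    if (max(tpl) - min(tpl) < 1e-6) {
      cls[i] <- "unclassified"; peak_lag[i] <- NA; fwhm[i] <- NA
      next
    }
    pk <- which.max(tpl)
    peak_lag[i] <- lags_ms[pk]
    fwhm[i] <- half_height_width(lags_ms, tpl, baseline = median(tpl))
    cls[i] <- if (abs(peak_lag[i]) <= 1) {
      if (fwhm[i] < fwhm_threshold_ms) "S_sync" else "B_sync"
    } else if (peak_lag[i] > 1) "F_async" else "R_async"
  }
  structure(list(templates = templates, cluster = ks, class_label = cls,
                 peak_lag_ms = peak_lag, fwhm_ms = fwhm,
                 lags_ms = lags_ms), class = "ccg_templates")
}

#' Per-pair class assignment with a random reference ordering
#'
#' Each clustered CCG row carries a class via its cluster; the final per-pair
#' label uses one seeded random choice of reference ordering, mirroring the
#' convention that the reference neuron of a pair is selected randomly for
#' population statistics.
#'
#' @param features a `ccg_features` object.
#' @param labels cluster labels per feature row.
#' @param templates a `ccg_templates` object.
#' @param seed RNG seed for the ordering choice.
#' @return Data frame `pair_index, ref, target, cluster, class_label`.
#' @export
assign_pair_classes <- function(features, labels, templates, seed = 1L) {
  stopifnot(inherits(features, "ccg_features"))
  set.seed(seed)
  out <- lapply(unique(features$pair_index), function(pi) {
    rows <- which(features$pair_index == pi)
    row <- if (length(rows) == 1) rows else sample(rows, 1)
    cl <- labels[row]
    data.frame(pair_index = pi, ref = features$ref[row],
               target = features$target[row], cluster = cl,
               class_label = templates$class_label[
                 match(cl, templates$cluster)])
  })
  do.call(rbind, out)
}

#' Narrow-peak monosynaptic candidate rule
#'
#' A significant CCG is a monosynaptic candidate when its corrected peak is
#' sharp and narrow - full width at half maximum below `width_ms` - and its
#' peak lag is nonzero (zero-lag synchrony points to common input instead).
#'
#' @param peak_features a `peak_features` list from [detect_peak()].
#' @param corrected_curve corrected CCG values over the full lag axis.
#' @param lags_ms lag axis.
#' @param width_ms width criterion (default 5 ms).
#' @return Logical scalar.
#' @export
monosynaptic_candidate <- function(peak_features, corrected_curve,
                                   lags_ms = seq(-100, 100), width_ms = 5) {
  if (peak_features$peak_lag_ms == 0) return(FALSE)
  w <- peak_half_width(corrected_curve, lags_ms, peak_features$peak_lag_ms)
  isTRUE(w < width_ms)
}

#' Width of a corrected-CCG peak at half height
#'
#' Full width at half maximum of the corrected CCG around a peak, measured
#' against a zero baseline (the corrected CCG is zero-mean under the jitter
#' null) within +-10 ms of the peak.
#'
#' @param corrected_curve corrected CCG values.
#' @param lags_ms lag axis.
#' @param peak_lag_ms peak location (default: argmax of the curve).
#' @return Width in ms (NA if the peak is not above baseline).
#' @export
peak_half_width <- function(corrected_curve, lags_ms = seq(-100, 100),
                            peak_lag_ms = NULL) {
  if (is.null(peak_lag_ms)) peak_lag_ms <- lags_ms[which.max(corrected_curve)]
  win <- abs(lags_ms - peak_lag_ms) <= 10
  half_height_width(lags_ms[win], corrected_curve[win], baseline = 0)
}
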