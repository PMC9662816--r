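# Population statistics over significant pairs: quantile-binned
# relationships, linear and exponential fits under MSE or MAE cost,
# distance matching, standardized regressions with IQR outlier trimming,
# class-composition tests, laminar logistic regression, and the
# simple-to-complex direction test.

#' Quantile-binned relationship between two pair variables
#'
#' Splits `x` into `n_bins` quantile bins and reports the chosen statistic of
#' `y` per bin with a seeded bootstrap 95% confidence interval.  Heavily tied
#' `x` values can collapse bins; collapsed bins are merged with a warning.
#'
#' @param x,y numeric vectors of equal length.
#' @param n_bins number of quantile bins (default 10).
#' @param stat `"mean"` or `"median"`.
#' @param n_boot bootstrap resamples for the CI (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Data frame `bin_center, stat, ci_lo, ci_hi, n`.
#' @export
binned_relationship <- function(x, y, n_bins = 10, stat = c("mean", "median"),
                                n_boot = 1000, seed = 1L) {
  stat <- match.arg(stat)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < n_bins) stop("need at least n_bins points", call. = FALSE)
  brk <- quantile(x, probs = seq(0, 1, length.out = n_bins + 1))
  ubrk <- unique(brk)
  if (length(ubrk) < length(brk)) {
    warning("tied x values collapsed ", length(brk) - length(ubrk),
            " bin boundary(ies); bins merged")
  }
  bin <- cut(x, ubrk, include.lowest = TRUE)
  fn <- if (stat == "mean") mean else median
  set.seed(seed)
  out <- lapply(levels(bin), function(b) {
    ix <- bin == b
    ys <- y[ix]
    bs <- vapply(seq_len(n_boot),
                 function(i) fn(ys[sample.int(length(ys), replace = TRUE)]),
                 numeric(1))
    data.frame(bin_center = fn(x[ix]), stat = fn(ys),
               ci_lo = unname(quantile(bs, 0.025)),
               ci_hi = unname(quantile(bs, 0.975)), n = sum(ix))
  })
  do.call(rbind, out)
}

#' Linear fit under MSE or MAE cost
#'
#' MSE gives ordinary least squares; MAE minimizes mean absolute error by
#' direct optimization from the OLS start (robust to gross outliers).
#' Pearson's r of (x, y) is reported alongside.
#'
#' @param x,y numeric vectors.
#' @param cost `"MSE"` or `"MAE"`.
#' @return list(slope, intercept, r, cost).
#' @export
fit_linear <- function(x, y, cost = c("MSE", "MAE")) {
  cost <- match.arg(cost)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  if (sd(x) == 0) stop("degenerate x", call. = FALSE)
  fit <- lm(y ~ x)
  beta <- coef(fit)
  if (cost == "MAE") {
    obj <- function(b) mean(abs(y - b[1] - b[2] * x))
    beta <- optim(beta, obj, method = "Nelder-Mead")$par
  }
  list(slope = unname(beta[2]), intercept = unname(beta[1]),
       r = if (sd(y) == 0) NA_real_ else cor(x, y), cost = cost)
}

#' Exponential decay fit
#'
#' Fits `y ~ a * exp(-x / lambda)`; reports both the e-fold constant lambda
#' and the half-distance `lambda * ln 2`.  The default MAE cost targets
#' median-based summaries (fit on binned medians upstream).  A fitted lambda
#' far beyond the data range is flagged as no-decay.
#'
#' @param x,y numeric vectors; `y` must be positive for initialization.
#' @param cost `"MAE"` (default) or `"MSE"`.
#' @return list(amplitude, lambda, half_distance, r, no_decay, cost).
#' @export
fit_exponential_decay <- function(x, y, cost = c("MAE", "MSE")) {
  cost <- match.arg(cost)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (any(y <= 0)) stop("y must be positive for an exponential-decay fit",
                        call. = FALSE)
  # log-linear start
  lf <- lm(log(y) ~ x)
  a0 <- exp(coef(lf)[1])
  slope0 <- coef(lf)[2]
  lam0 <- if (slope0 < 0) -1 / slope0 else diff(range(x)) * 100 + 1
  obj <- function(p) {
    pred <- exp(p[1]) * exp(-x / exp(p[2]))
    if (cost == "MAE") mean(abs(y - pred)) else mean((y - pred)^2)
  }
  fit <- optim(c(log(a0), log(lam0)), obj, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
  a <- unname(exp(fit$par[1])); lam <- unname(exp(fit$par[2]))
  no_decay <- lam > 100 * max(diff(range(x)), 1e-12)
  list(amplitude = a, lambda = if (no_decay) Inf else lam,
       half_distance = if (no_decay) Inf else lam * log(2),
       r = if (sd(y) == 0) NA_real_ else cor(x, y),
       no_decay = no_decay, cost = cost)
}

#' Distance-matched pairing of significant CCGs
#'
#' Sorts significant pairs by cortical distance and matches the 1st with the
#' 2nd, the 3rd with the 4th, and so on (an odd leftover is dropped and
#' logged), then reports within-match differences of |peak lag|, peak
#' efficacy, and signal correlation, their correlations, and the fraction of
#' matches whose distance difference is below `close_um`.
#'
#' @param pairs data frame with `distance_um`, `peak_lag_ms`,
#'   `peak_efficacy`, and `r_ori` columns (significant pairs only).
#' @param close_um audit tolerance on matched distance differences
#'   (default 2).
#' @return list(matches, frac_close, cor_lag, cor_eff, n_dropped) where
#'   `cor_lag`/`cor_eff` are `cor.test` results of d|lag| and d(efficacy)
#'   against d(r_ori).
#' @export
distance_match <- function(pairs, close_um = 2) {
  stopifnot(nrow(pairs) >= 2)
  ord <- order(pairs$distance_um)
  n <- length(ord)
  n_use <- n - n %% 2L
  if (n_use < n) message("distance matching dropped 1 leftover pair")
  i1 <- ord[seq(1, n_use, by = 2)]
  i2 <- ord[seq(2, n_use, by = 2)]
  matches <- data.frame(
    d_distance_um = pairs$distance_um[i2] - pairs$distance_um[i1],
    d_abs_lag_ms = abs(pairs$peak_lag_ms[i2]) - abs(pairs$peak_lag_ms[i1]),
    d_efficacy = pairs$peak_efficacy[i2] - pairs$peak_efficacy[i1],
    d_r_ori = pairs$r_ori[i2] - pairs$r_ori[i1])
  safe_cor <- function(a, b) {
    if (sum(complete.cases(a, b)) < 3 || sd(a) == 0 || sd(b) == 0) NULL
    else cor.test(a, b)
  }
  list(matches = matches,
       frac_close = mean(abs(matches$d_distance_um) < close_um),
       cor_lag = safe_cor(matches$d_abs_lag_ms, matches$d_r_ori),
       cor_eff = safe_cor(matches$d_efficacy, matches$d_r_ori),
       n_dropped = n - n_use)
}

iqr_keep <- function(y, k = 1.5) {
  qs <- quantile(y, c(0.25, 0.75), na.rm = TRUE)
  iqr <- qs[2] - qs[1]
  y >= qs[1] - k * iqr & y <= qs[2] + k * iqr
}

#' Standardized linear regression of peak lag or efficacy
#'
#' Ordinary least squares of the target on z-scored pair distance and signal
#' correlation, after removing target outliers by the 1.5 IQR rule.
#' Standardization makes coefficients comparable: each is the change in the
#' target per 1 SD of the predictor.  Peak-lag regressions use |peak lag|.
#'
#' @param pairs data frame with `distance_um`, `r_ori`, `peak_lag_ms`,
#'   `peak_efficacy`.
#' @param target `"peak_lag"` or `"peak_efficacy"`.
#' @param absolute_lag take |peak_lag_ms| as the lag target (default TRUE,
#'   the population convention); set FALSE when the column already holds the
#'   absolute lag.
#' @return list(coefficients, intercept, r_squared, n, removed).
#' @export
fit_standardized_regression <- function(pairs,
                                        target = c("peak_lag",
                                                   "peak_efficacy"),
                                        absolute_lag = TRUE) {
  target <- match.arg(target)
  y <- if (target == "peak_lag") {
    if (absolute_lag) abs(pairs$peak_lag_ms) else pairs$peak_lag_ms
  } else pairs$peak_efficacy
  ok <- complete.cases(y, pairs$distance_um, pairs$r_ori)
  y <- y[ok]
  d <- pairs$distance_um[ok]; r <- pairs$r_ori[ok]
  if (length(y) < 10) stop("need at least 10 pairs", call. = FALSE)
  if (abs(cor(d, r)) >= 1 - 1e-12) stop("collinear predictors", call. = FALSE)
  keep <- iqr_keep(y)
  y2 <- y[keep]
  zd <- as.numeric(scale(d[keep]))
  zr <- as.numeric(scale(r[keep]))
  fit <- lm(y2 ~ zd + zr)
  list(coefficients = c(pair_distance = unname(coef(fit)[2]),
                        r_ori = unname(coef(fit)[3])),
       intercept = unname(coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = sum(keep), removed = sum(!keep))
}

#' Class-composition tests across layers
#'
#' For each CCG class: the proportion of pairs whose two units share a
#' cortical layer, with a one-proportion z-test against 0.5; a class x
#' same/different-layer contingency table with a chi-squared test; and
#' pairwise Wilcoxon rank-sum tests of distance and signal correlation
#' between classes, Bonferroni-corrected within each family (one family per
#' output table).
#'
#' @param pairs data frame with `class_label`, `layer_ref`, `layer_target`,
#'   `distance_um`, `r_ori`.
#' @param alpha nominal level for the corrected flags (default 0.05).
#' @return list(within_layer, contingency, chisq, ranksum_distance,
#'   ranksum_r_ori).
#' @export
class_composition_tests <- function(pairs, alpha = 0.05) {
  stopifnot(all(c("class_label", "layer_ref", "layer_target") %in%
                  names(pairs)))
  pairs <- pairs[!is.na(pairs$class_label), , drop = FALSE]
  same <- pairs$layer_ref == pairs$layer_target
  classes <- sort(unique(pairs$class_label))

  within <- do.call(rbind, lapply(classes, function(cl) {
    ix <- pairs$class_label == cl
    zt <- one_proportion_z_test(sum(same[ix]), sum(ix))
    data.frame(class_label = cl, n = sum(ix),
               prop_within_layer = zt$estimate, z = zt$z,
               p_value = zt$p_value,
               p_bonferroni = min(1, zt$p_value * length(classes)))
  }))
  within$significant <- within$p_bonferroni < alpha

  tab <- table(pairs$class_label, ifelse(same, "within", "between"))
  cs <- suppressWarnings(chisq.test(tab))
  unreliable <- any(cs$expected < 5)

  ranksum <- function(v) {
    cmb <- combn(classes, 2)
    out <- lapply(seq_len(ncol(cmb)), function(i) {
      a <- v[pairs$class_label == cmb[1, i]]
      b <- v[pairs$class_label == cmb[2, i]]
      p <- suppressWarnings(wilcox.test(a, b)$p.value)
      data.frame(class_a = cmb[1, i], class_b = cmb[2, i], p_value = p,
                 p_bonferroni = min(1, p * ncol(cmb)))
    })
    res <- do.call(rbind, out)
    res$significant <- res$p_bonferroni < alpha
    res
  }

  list(within_layer = within,
       contingency = tab,
       chisq = list(statistic = unname(cs$statistic),
                    p_value = cs$p.value, df = unname(cs$parameter),
                    unreliable = unreliable),
       ranksum_distance = if (length(classes) > 1) ranksum(pairs$distance_um),
       ranksum_r_ori = if (length(classes) > 1 && "r_ori" %in% names(pairs))
         ranksum(pairs$r_ori))
}

# Ridge-penalized logistic fallback for separated data.
penalized_logistic <- function(X, y, lambda = 1e-3) {
  nll <- function(b) {
    eta <- X %*% b
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
      lambda * sum(b[-1]^2)
  }
  fit <- optim(rep(0, ncol(X)), nll, method = "BFGS")
  fit$par
}

#' Logistic regression of class membership on distance and layer pairing
#'
#' Within a band of pair distances where same- and different-layer pairs
#' overlap, fits a maximum-likelihood logistic regression of membership in
#' the queried class on pair distance (um) and a same-layer indicator.
#' Complete separation is flagged and handled with a ridge-penalized fit.
#'
#' @param pairs data frame with `class_label`, `distance_um`, `layer_ref`,
#'   `layer_target`.
#' @param class the CCG class to predict membership of.
#' @param distance_range inclusive distance band in um (default c(86, 310)).
#' @return list(coefficients, se, p_values, n, separated).
#' @export
layer_logistic_regression <- function(pairs, class,
                                      distance_range = c(86, 310)) {
  sel <- pairs$distance_um >= distance_range[1] &
    pairs$distance_um <= distance_range[2] & !is.na(pairs$class_label)
  sub <- pairs[sel, , drop = FALSE]
  if (nrow(sub) < 20) stop("fewer than 20 pairs in the distance range",
                           call. = FALSE)
  y <- as.integer(sub$class_label == class)
  same <- as.integer(sub$layer_ref == sub$layer_target)
  fit <- suppressWarnings(glm(y ~ sub$distance_um + same,
                              family = binomial()))
  sm <- suppressWarnings(summary(fit))
  separated <- !fit$converged || any(abs(coef(fit)[-1]) > 20)
  coefs <- coef(fit)
  if (separated) {
    X <- cbind(1, sub$distance_um, same)
    coefs <- penalized_logistic(X, y)
    names(coefs) <- names(coef(fit))
  }
  list(coefficients = c(intercept = unname(coefs[1]),
                        distance = unname(coefs[2]),
                        same_layer = unname(coefs[3])),
       se = c(distance = sm$coefficients[2, 2],
              same_layer = sm$coefficients[3, 2]),
       p_values = c(distance = sm$coefficients[2, 4],
                    same_layer = sm$coefficients[3, 4]),
       n = nrow(sub), separated = separated)
}

#' Forward versus reverse classes among simple-to-complex pairs
#'
#' Restricts to significant pairs whose reference unit is a simple cell and
#' whose target is a complex cell, and tests whether forward (`F_async`)
#' CCGs outnumber reverse (`R_async`) ones with a one-proportion z-test
#' against 0.5.
#'
#' @param pairs data frame with `class_label` and per-pair `cell_class_ref`,
#'   `cell_class_target`.
#' @return list(n_forward, n_reverse, proportion_forward, z, p_value), or
#'   an empty list when no such pairs exist.
#' @export
simple_complex_direction_test <- function(pairs) {
  sel <- pairs$cell_class_ref == "simple" &
    pairs$cell_class_target == "complex" & !is.na(pairs$class_label)
  sub <- pairs[sel & pairs$class_label %in% c("F_async", "R_async"), ,
               drop = FALSE]
  if (!nrow(sub)) return(list(n_forward = 0L, n_reverse = 0L))
  nf <- sum(sub$class_label == "F_async")
  nr <- sum(sub$class_label == "R_async")
  zt <- one_proportion_z_test(nf, nf + nr)
  list(n_forward = nf, n_reverse = nr, proportion_forward = zt$estimate,
       z = zt$z, p_value = zt$p_value)
}
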