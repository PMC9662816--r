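# Current-source-density profile from trial-averaged LFP and depth-to-layer
# assignment anchored at the layer 4c/5 border.
#
# Depth convention: the depth axis is signed micrometers, increasing toward
# the cortical surface ("up"); "below" a feature means smaller depth values.
# Sinks are negative (conductivity is set to 1 in arbitrary units - only the
# sink geometry matters here).

#' LFP profile container
#'
#' @param depth_um uniformly spaced, strictly increasing depth grid (um).
#' @param time_s time grid (s), 0 at stimulus onset.
#' @param phi trial-averaged potential matrix (depth x time).
#' @return An `lfp_profile` list.
#' @export
lfp_profile <- function(depth_um, time_s, phi) {
  stopifnot(is.matrix(phi), nrow(phi) == length(depth_um),
            ncol(phi) == length(time_s))
  h <- diff(depth_um)
  if (length(h) < 4 || any(abs(h - h[1]) > 1e-6 * abs(h[1]))) {
    stop("depth grid must be uniform with at least 5 samples", call. = FALSE)
  }
  if (h[1] <= 0) stop("depth grid must be strictly increasing", call. = FALSE)
  structure(list(depth_um = depth_um, time_s = time_s, phi = phi,
                 spacing_um = h[1]), class = "lfp_profile")
}

#' Current source density via the five-point second-derivative stencil
#'
#' CSD(z_i) = -(phi_{i-2} - 2 phi_i + phi_{i+2}) / (2h)^2, defined on the
#' interior depths (two trimmed at each margin).  Negative values are sinks.
#'
#' @param lfp an `lfp_profile`.
#' @return A `csd_profile`: list(depth_um, time_s, csd, spacing_um).
#' @export
compute_csd <- function(lfp) {
  stopifnot(inherits(lfp, "lfp_profile"))
  n <- length(lfp$depth_um)
  if (n < 5) stop("need at least 5 depth samples", call. = FALSE)
  i <- 3:(n - 2)
  h2 <- (2 * lfp$spacing_um)^2
  csd <- -(lfp$phi[i - 2, , drop = FALSE] - 2 * lfp$phi[i, , drop = FALSE] +
             lfp$phi[i + 2, , drop = FALSE]) / h2
  structure(list(depth_um = lfp$depth_um[i], time_s = lfp$time_s, csd = csd,
                 spacing_um = lfp$spacing_um), class = "csd_profile")
}

#' Gaussian spatial smoothing of a CSD profile
#'
#' Smooths along the depth axis with a Gaussian kernel (reflected
#' boundaries) to reduce electrode-impedance artifacts.
#'
#' @param csd a `csd_profile`.
#' @param sigma_um kernel SD in um (default 120; 0 is the identity).
#' @return The smoothed `csd_profile`.
#' @export
smooth_csd <- function(csd, sigma_um = 120) {
  stopifnot(inherits(csd, "csd_profile"), sigma_um >= 0)
  if (sigma_um == 0) return(csd)
  out <- csd
  out$csd <- apply(csd$csd, 2, gaussian_smooth, spacing = csd$spacing_um,
                   sigma = sigma_um)
  if (!is.matrix(out$csd)) out$csd <- matrix(out$csd, nrow = 1)
  out
}

#' Locate the laminar anchor from the major CSD sink
#'
#' Time-averages the (smoothed) CSD over the post-stimulus response window,
#' finds the major sink (the most negative value), and returns the
#' sink-to-source reversal point immediately below it (linear interpolation
#' between depth samples).  This zero crossing is the layer 4c/5 border
#' anchor.
#'
#' @param csd a `csd_profile` (smooth first).
#' @param response_window time window (s) to average over
#'   (default c(0.02, 0.1)).
#' @return Anchor depth in um.
#' @export
locate_anchor <- function(csd, response_window = c(0.02, 0.1)) {
  stopifnot(inherits(csd, "csd_profile"))
  tsel <- csd$time_s >= response_window[1] & csd$time_s <= response_window[2]
  if (!any(tsel)) stop("response window outside the time grid", call. = FALSE)
  prof <- rowMeans(csd$csd[, tsel, drop = FALSE])
  if (all(prof >= 0)) stop("no sink (negative CSD) found; manual anchor required",
                           call. = FALSE)
  s <- which.min(prof)
  # walk downward (decreasing depth) to the first sign reversal
  j <- s
  while (j > 1 && prof[j - 1] < 0) j <- j - 1
  if (j == 1) stop("no sink-to-source reversal below the major sink; manual anchor required",
                   call. = FALSE)
  # zero crossing between depths j-1 (source side) and j (sink side)
  z1 <- csd$depth_um[j - 1]; z2 <- csd$depth_um[j]
  v1 <- prof[j - 1]; v2 <- prof[j]
  z1 + (0 - v1) * (z2 - z1) / (v2 - v1)
}

#' Assign cortical layers from depths and the laminar anchor
#'
#' Stacks the laminar thickness table around the anchor (the layer 4c/5
#' border, i.e. the top of layer "5"), and labels each depth by the layer
#' interval containing it.  Intervals are half-open `(bottom, top]`, so a
#' unit exactly at the anchor is assigned to layer 5 (the lower side).
#' Depths outside the table's span are labeled `"unknown"`.
#'
#' @param depths_um numeric vector of unit depths (um, increasing toward the
#'   surface).
#' @param anchor_um anchor depth (um).
#' @param thickness_table named thicknesses, superficial to deep; see
#'   [default_thickness_table()].
#' @param anchor_layer name of the layer whose *top* sits at the anchor
#'   (default `"5"`).
#' @return Character vector of layer labels.
#' @export
assign_layers <- function(depths_um, anchor_um,
                          thickness_table = default_thickness_table(),
                          anchor_layer = "5") {
  if (any(thickness_table <= 0)) stop("overlapping/invalid thickness table",
                                      call. = FALSE)
  ai <- match(anchor_layer, names(thickness_table))
  if (is.na(ai)) stop("anchor_layer not in thickness table", call. = FALSE)
  # boundary depths from the top of the most superficial layer downward
  tops <- if (ai > 1) {
    anchor_um + rev(cumsum(rev(thickness_table[seq_len(ai - 1)])))
  } else numeric(0)
  bounds <- c(tops, anchor_um,
              anchor_um - cumsum(thickness_table[ai:length(thickness_table)]))
  # bounds: top of layer 1, ..., top of last layer, bottom of last layer
  labels <- names(thickness_table)
  out <- rep("unknown", length(depths_um))
  for (i in seq_along(labels)) {
    out[depths_um > bounds[i + 1] & depths_um <= bounds[i]] <- labels[i]
  }
  out
}

#' Simulate a laminar LFP with a planted sink (synthetic test fixture)
#'
#' Forward model for validating the CSD chain: a true CSD is defined as a
#' Gaussian sink centered above the 4c/5 border plus a balancing source
#' below it, and the potential is obtained by double integration, so the
#' five-point stencil recovers the planted geometry.  Purely synthetic.
#'
#' @param depth_um depth grid (uniform, increasing).
#' @param time_s time grid.
#' @param sink_center_um,sink_sd_um sink position and width.
#' @param source_offset_um center of the balancing source below the sink.
#' @param amplitude sink amplitude (arbitrary units).
#' @param onset_s response onset time.
#' @return list(lfp = `lfp_profile`, true_csd, anchor_true_um).
#' @export
simulate_lfp_sink <- function(depth_um = seq(-900, 1100, by = 20),
                              time_s = seq(-0.05, 0.2, by = 0.002),
                              sink_center_um = 150, sink_sd_um = 120,
                              source_offset_um = -250, amplitude = 1,
                              onset_s = 0.02) {
  sink <- -amplitude * exp(-0.5 * ((depth_um - sink_center_um) / sink_sd_um)^2)
  source <- amplitude * exp(-0.5 *
    ((depth_um - sink_center_um - source_offset_um) / sink_sd_um)^2)
  true_csd <- sink + source
  # analytic double integral of a Gaussian bump (avoids the half-sample bias
  # a cumulative-sum quadrature would introduce): phi'' = -csd
  dint2 <- function(z, c, s) {
    u <- (z - c) / s
    s^2 * sqrt(2 * pi) * (u * stats::pnorm(u) + stats::dnorm(u))
  }
  phi_z <- amplitude * dint2(depth_um, sink_center_um, sink_sd_um) -
    amplitude * dint2(depth_um, sink_center_um + source_offset_um, sink_sd_um)
  tmod <- ifelse(time_s >= onset_s, 1 - exp(-(time_s - onset_s) / 0.02), 0)
  phi <- outer(phi_z, tmod)
  # true anchor: zero crossing of true_csd below the sink center
  s <- which.min(true_csd)
  j <- s
  while (j > 1 && true_csd[j - 1] < 0) j <- j - 1
  anchor_true <- {
    z1 <- depth_um[j - 1]; z2 <- depth_um[j]
    v1 <- true_csd[j - 1]; v2 <- true_csd[j]
    z1 + (0 - v1) * (z2 - z1) / (v2 - v1)
  }
  list(lfp = lfp_profile(depth_um, time_s, phi), true_csd = true_csd,
       anchor_true_um = anchor_true)
}
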