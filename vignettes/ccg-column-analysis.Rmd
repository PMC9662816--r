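---
title: "Jitter-corrected CCG analysis of a cortical column: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Jitter-corrected CCG analysis of a cortical column: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ccgcolumn)
```

## The model and its assumptions

The package treats a columnar recording as a set of point processes observed
on a common trial structure: each unit's spikes are binned into binary 1 ms
indicators `x_ji(t)` over an analysis window inside each stimulus
presentation. Three assumptions do all the work:

1. **Stationarity across trials of the stimulus-locked component.** The
   across-trial PSTH is a consistent estimate of the stimulus-locked firing
   rate; everything locked to the stimulus is nuisance for pairwise
   inference.
2. **Separation of timescales.** Genuine synaptic or common-input
   coordination lives at millisecond lags; shared rate fluctuations
   (arousal, up/down states, gamma envelopes) live at tens of milliseconds
   and beyond. The 25 ms jitter window is the cut between the two: the
   jitter null preserves each trial's spike count inside every 25 ms window
   and the across-trial PSTH, so subtracting the jitter-expected CCG removes
   both stimulus locking and all correlation slower than the window.
3. **Binary bins.** At 1 ms resolution, multiple spikes per bin are rare for
   cortical rates; they are clipped to 1 and counted (`clipped` in
   `bin_spikes()`), keeping the CCG a coincidence-per-spike measure.

The CCG normalization divides by `theta(tau) = N - |tau|` (overlap
correction) and by the geometric mean of the two units' rates **in spikes
per bin**. The spikes-per-bin convention makes the CCG dimensionless and
puts peak efficacy on the scale of transmission probability: for a planted
connection with per-spike probability `p`, the corrected peak is
approximately `p * sqrt(lambda_pre / lambda_post)`, which the acceptance
suite verifies to within 20%.

The jitter-expected CCG is computed in closed form: under independent
jitter of both trains, the expectation factorizes, so the same correlogram
formula is applied to the two expected jittered rate arrays
`r_ji(t) = n_ji(w(t)) * PSTH_j(t) / sum_{t' in w(t)} PSTH_j(t')`. A
Monte-Carlo mode (explicit jitter resampling) is retained purely as an
independent oracle; the test suite checks the two agree within Monte-Carlo
error at every lag.

## Significance and peak features

A pair is significant when the corrected CCG's peak exceeds 7 SDs of the
flank noise (50 <= |tau| <= 100 ms, 102 bins) *and* the global maximum of
the corrected curve lies within 10 ms of zero. The second clause matters: a
curve whose largest excursion sits at, say, 12 ms is not a zero-lag
interaction even if some bin inside the window is also large. Troughs are
screened symmetrically (z below -7) so inhibitory-style counts can be
reported, though the generator plants no inhibition. Exact ties in the peak
search are broken toward smaller |tau|, then toward negative tau, and the
choice is deterministic. Pairs with zero flank SD are flagged
(`degenerate_noise`) rather than classified.

At 7 SDs the false-positive rate on independent Poisson pairs is far below
1% (the acceptance suite bounds it at 1% over 100 pairs); the threshold is
deliberately conservative because a columnar recording tests tens of
thousands of pairs.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| bin width | 0.001 | s | forced by the ±10 ms, 21-feature classification window |
| analysis window | 0.4–1 | s | skips the onset transient |
| jitter window | 25 | ms | timescale cut; must tile the window (600/25 = 24) |
| significance | 7 | flank SD | conservative for ~10^4 simultaneous pairs |
| peak lag window | 10 | ms | zero-lag interaction criterion |
| rate inclusion | >= 3 | spikes/s | low-rate units give unstable CCG normalizations; bound inclusive |
| double counts | 50 µm, 0.167 ms, 20% | — | spike-sorting split-unit screen; flagged pairs excluded from the significant set (config-switchable) |
| monosynaptic width | < 5 | ms | narrow-peak candidate rule, nonzero lag required |
| logistic band | 86–310 | µm | distance range where same- and different-layer pairs overlap |

## What the synthetic column emulates — and what it does not

`column_config()` defaults are the package's stated world: 36 drift
directions in 10° steps, 1 s trials repeated 5 times (10 in the tuning
recovery tests; both counts are standard), lognormal background rates
(median 8 spikes/s), von Mises direction tuning with kappa = 8 and a 20
spikes/s tuned drive (peak rates ~28 spikes/s, direction half-width ~21°),
a shared column preference with 15° scatter, 30% simple cells whose entire
response is half-wave modulated at the 4 Hz grating frequency (analytic
F1/F0 = pi/2), a 2x onset transient decaying in 50 ms, and multiplicative
slow shared modulation (200 ms timescale, 30% amplitude, random phase per
trial) that only the jitter correction can remove.

Planted interactions: 30 monosynaptic connections (p = 0.25, delays 1–4 ms,
0.5 ms jitter) and 10 common-input pairs (hidden 20 Hz source, copy
probability 0.5, 1 ms dispersion). Pair selection prefers nearby depths
(exponential kernel, 200 µm scale) and similar tuning. Two optional knobs
couple interaction parameters to distance — `mono_delay_rate_ms_per_um`
and `efficacy_half_distance_um` — so distance–lag and distance–efficacy
relationships can be planted when a test needs them; they are off by
default so that planted-pair recovery is uniform.

Two defaults were set by analytic power calculation, not by tuning to test
outcomes: common input at copy probability 0.3 with 2 ms dispersion has an
expected corrected-CCG peak of only ~4 flank SDs — undetectable at the 7 SD
criterion *by construction* — so the default common input is the strong,
sharp regime that produces the sharply synchronous class. Similarly, the
tuned drive must reach ~20 spikes/s for an argmax estimator on a 10° grid
with 5 repeats to land within ±10° of the true preference in ≥95% of units.

What a green test does **not** establish: the generator is a thinned
inhomogeneous Bernoulli process, not a biophysical model. It has no
refractory periods, no inhibition, no burst structure, no cross-column
geometry (distance is purely vertical), and the slow modulation is
sinusoidal rather than 1/f. Recovery results validate the *analysis chain*,
not any claim about cortex.

## Shape classification

Significant corrected CCGs are restricted to ±10 ms (21 features), included
in both pair orderings (so the feature set is closed under lag reversal and
asymmetric templates come in mirror pairs), z-scored per curve (shape, not
magnitude), embedded to 3 dimensions with t-SNE (perplexity 30, 1000
iterations, seeded; backed by Rtsne), and clustered with k-means (k = 1–10,
50 restarts, 100 iterations). Model selection takes the k whose silhouette
is within 0.02 of the maximum and, within that plateau, the largest
explained variance `eta_k = (TSS - WCSS_k)/TSS`; this encodes "silhouette
peaks at a plateau, the elbow criterion breaks the tie upward". The
`eta` formula uses squared Euclidean norms — the standard variance
decomposition — even though an unsquared norm sometimes appears in print;
percent-of-variance semantics requires squares.

Cluster templates (mean z-scored curves) are labeled automatically: peak
within ±1 ms of zero is synchronous, split sharp/broad at a 4 ms full width
at half maximum; later peaks are forward, earlier are reverse; flat
templates surface as `unclassified` rather than being forced into a class.
For population statistics each pair contributes once, with a seeded random
choice of reference ordering. The embedding's contract is cluster
recoverability under a fixed seed, not particular coordinates; the
acceptance suite requires adjusted Rand ≥ 0.8 on a planted 4-template
mixture and exact agreement of `eta`/silhouette with brute-force oracles on
small fixtures.

## Numerical choices and degenerate inputs

* Bins are half-open `[t, t + 1 ms)`; a 1e-9-bin guard absorbs floating
  representation error at exact boundaries.
* Raw CCG numerators are integer coincidence counts (sparse difference
  tabulation), so mirror symmetry `CCG_{j-k}(tau) = CCG_{k-j}(-tau)` is
  bit-exact; the jittered expectation is computed once per unordered pair
  and mirrored, never recomputed, so the identity holds for all three
  variants.
* FFT lengths are padded per trial to 5-smooth integers; cross-trial
  products are structurally impossible (inter-trial gap exceeds the maximum
  lag).
* Jitter windows with zero PSTH mass but nonzero count (reachable only via
  clipping pathologies) distribute the count uniformly.
* MAE fits (exponential decay, robust linear) start from the least-squares
  solution and refine by Nelder–Mead; an exponential fit whose scale
  exceeds 100x the data range is reported as no-decay with infinite
  half-distance rather than a spurious number.
* Logistic regressions that separate completely fall back to a small ridge
  penalty and are flagged `separated`.
* The distance-matching audit tolerance (2 µm) is only attainable when the
  pair density exceeds roughly 2 pairs/µm near every distance; the
  acceptance fixture (2000 pairs within 400 µm) states that world
  explicitly.

## Open design decisions taken

* The minimum-rate inclusion filter is applied over the analysis window (not
  the whole recording), with an inclusive bound.
* F1 is computed on the pooled-repeat PSTH at the preferred direction over
  the full 1 s stimulus (integer cycles at 4 Hz avoid spectral leakage);
  per-trial F1 averaging is possible but not the default.
* Signal correlations use full-stimulus responses (no latency offset);
  evoked-rate summaries use a 30 ms latency. Both windows are arguments.
* "GLM" for peak lag/efficacy means OLS on z-scored predictors after
  1.5·IQR trimming of the target; peak-lag fits use |lag| by default, with
  a switch (`absolute_lag`) for targets that are already magnitudes.
* Flagged double-count pairs stay in the pair table with their flag but are
  excluded from the significant set by default.

## Known limitations

* The analytic jitter null assumes both trains jittered independently; a
  one-train-jitter variant is not implemented.
* Inhibitory interactions are detected (trough screening) but never
  generated, so trough handling is validated only by the sign-flip identity.
* t-SNE coordinates are seed-stable but not portable across BLAS/compiler
  variations; only clustering-level results should be compared across
  machines.
* The CSD anchor assumes a single dominant sink with a sign reversal below
  it; profiles without a reversal require a manual anchor, and the shipped
  laminar thickness table is illustrative, not histological.
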