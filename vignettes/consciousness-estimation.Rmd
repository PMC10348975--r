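---
title: "Estimating consciousness levels from EEG by soft clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating consciousness levels from EEG by soft clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients with disorders of consciousness (coma, vegetative state /
unresponsive wakefulness syndrome, minimally conscious state) cannot report
their own state, and behavioural scales probe it only intermittently.
`consclust` estimates a continuous consciousness level over time from the
EEG alone. The working hypothesis is that conscious periods show, relative
to unconscious ones:

* elevated θ (4–8 Hz) and β (12–30 Hz) relative power,
* a 95% spectral edge frequency (SEF95) above the α band,
* larger signal complexity (a rounder Poincaré cloud, richer Lempel–Ziv
  phrase structure),
* stronger linear and nonlinear inter-channel coupling in the θ band.

Seven features capture these signatures per sliding window; two soft
clustering methods then partition the windows into a *conscious* and an
*unconscious* cluster, and the membership of each window in the conscious
cluster — averaged across the two methods — is the estimated consciousness
level in [0, 1].

```{r, eval = FALSE}
library(consclust)

fit <- recording |>
  bandpass_filter() |>          # 0.5–45 Hz, 3rd-order Butterworth
  extract_features() |>         # 7 features per 3-s window (1-s hop)
  estimate_consciousness(seed = 1)

autoplot(fit)
```

## Pipeline and parameters

**Filtering.** Each channel is band-pass filtered 0.5–45 Hz with a
third-order Butterworth filter; no artifact rejection is applied (these
patients' recordings cannot be cleaned by rejecting "abnormal" epochs
without discarding the signal of interest). The filter is applied
forward–backward by default. Zero-phase filtering keeps every feature
aligned in time with external scoring; a causal single pass is available
via `zero_phase = FALSE` for strictly online settings, at the cost of a
frequency-dependent group delay.

**Segmentation.** 3-s windows sliding by 1 s. A trailing partial window is
dropped rather than padded: all features are defined on fixed-length
segments, and the Welch sub-window length is derived from the segment
length. Sample indexing is 0-based and half-open.

**Spectral features.** The PSD of each window/channel is estimated by
Welch's method with Hamming sub-windows of 1/8 the segment length and 50%
overlap. Relative power of a band is the ratio of discrete PSD sums, with
the denominator running over 0–45 Hz (the filter's pass limit); SEF95 is
the first grid frequency at which the cumulative PSD reaches 95% of the
total, normalized by 45 Hz. Discrete grid sums (not trapezoidal
integration) and the first-bin-crossing convention (no interpolation) are
used, matching the summation form of the definitions; a bin belongs to a
band when its center lies inside the band limits, inclusive. Note that at
500 Hz a 1500-sample window yields 187-sample sub-windows, i.e. a ≈2.67 Hz
grid, so the θ band spans only one or two bins. This coarseness is accepted
as part of the stated estimator settings; it broadens, but does not bias
away, the conscious/unconscious contrast.

**Complexity features.** The Poincaré plot draws `x(t)` against
`x(t + τ)`, τ = 1 sample. The ellipsoid radius ratio ERR = SD1/SD2 is
computed in closed form from the standard deviations of `x(t)` and of the
lag-τ differences, with the standard deviations taken over the paired range
`t = 1..n−τ` so the closed form coincides with the geometric definition on
the plotted pairs. ERR ≈ 1 indicates randomness (round cloud), ERR → 0
linear structure. Lempel–Ziv complexity is computed on the window binarized
at the mean absolute Hilbert transform (bit 1 where `|x_h(t)|` exceeds its
mean; ties to 0), then parsed with the exhaustive LZ76 scheme
(Kaspar–Schuster), the standard choice in the EEG complexity literature;
an LZ78 dictionary parse is available behind `scheme = "lz78"` for
comparison. The count is normalized by `n / log2(n)` so long random
sequences score near 1. The binarization thresholds the Hilbert transform
itself, not the analytic-signal envelope, following the definition as
printed; the envelope variant would emphasize amplitude rather than phase
structure.

**Connectivity features.** Coherency is the normalized cross-spectrum; only
its imaginary part is retained, since instantaneous (volume-conducted)
mixing contributes only to the real part. Cross- and auto-spectra reuse the
Welch scheme above. The per-pair scalar is the mean of |Im(coherency)| over
the θ-band bins, and pairs are averaged; magnitudes are averaged because
signed lead/lag contributions across bins and pairs would cancel. wSMI maps
each channel to its sequence of ordinal patterns of `k = 3` samples
τ = 16 ms apart (8 samples at 500 Hz; for other rates τ is rounded to the
nearest sample with a warning above 10% rounding error), then computes the
mutual information of the empirical joint pattern distribution, normalized
by log k!. Pattern pairs that are identical or sign-opposite get weight
zero, discounting common-source coupling. The estimate is floored at 0:
the weighted empirical sum can dip microscopically below zero by sampling
noise, while the quantity's defined range is [0, 1]. Ties in ranking are
broken by temporal order (the earlier sample ranks lower), making the
symbolization total. wSMI is computed on the broadband-filtered signal; its
θ selectivity comes from the lag, not from an extra θ filter. Note a
tension inherited from the measure itself: "completely dependent" *identical*
signals score 0, not 1, because identical patterns carry zero weight — the
weighting is deliberate (volume conduction), and a deterministic
non-identical pattern correspondence does reach 1.

**Feature matrix.** Per-channel features are averaged across channels, and
pair features across all unordered pairs, giving seven numbers per window:
`theta_rp`, `beta_rp`, `sef95`, `err`, `lzc`, `icoh_theta`, `wsmi_theta`.
Degenerate windows (zero power, constant signal) yield NaN and are excluded
from clustering; their trace values are NA.

## Soft clustering

Features are min–max normalized to [0, 1] per column over the recording's
finite rows (a constant column is set to 0.5 with a warning and effectively
ignored by the distance geometry). Two clusters (`N = 2`) represent
conscious and unconscious states.

**Fuzzy c-means.** Memberships are initialized uniformly at random (seeded,
row-normalized); centroid and membership updates alternate until the
objective `J_m` — the membership-weighted sum of squared distances with
fuzzifier `m = 2` — improves by less than `eps = 1e-5`, up to 1000
iterations. `eps` is an absolute improvement threshold, reading the
stopping rule as "minimum improvement of the objective". A point coincident
with a centroid receives membership exactly 1 (the update's singularity,
resolved by its limit). Since the objective is non-convex and the
initialization random, the best of 5 seeded restarts (lowest final `J_m`)
is kept, which also stabilizes cluster labels across runs. A user-supplied
initial membership matrix bypasses the restarts for deterministic runs.

**Gaussian mixture by EM.** A full-covariance two-component mixture is
fitted by EM with the same stopping rule (absolute log-likelihood
improvement below 1e-5, max 1000 iterations). Initial responsibilities come
from a k-means++-style seeding; 5 seeded starts are run and the best final
log-likelihood kept. Each covariance carries a 1e-6 diagonal ridge so that
tight clusters on normalized features cannot produce singular covariances;
the posteriors are the soft memberships.

**Conscious-cluster labeling.** The hypothesis list implies the conscious
cluster should have the *higher* centroid in every feature. Lifting this to
the 7-dimensional centroid, the cluster that is higher in the majority of
coordinates is labeled conscious; exact ties fall back to the higher SEF95
coordinate (the single most interpretable marker, with anchored anaesthesia
semantics), then to the higher centroid mean. Labeling is done per method
independently, then the two conscious-membership traces are averaged
sample-wise into the final consciousness level.

## Evaluation

`spearman_contributions()` reports the Spearman ρ (and p-value) between
each feature and each trace — how much each EEG signature drives the final
estimate; correlations with p > 0.05 are flagged. `intercluster_distance()`
is the Euclidean distance between the two centroids on the normalized
features, overall or per feature pair; small distances mean the clusters
barely separate and the trace should not be trusted.
`accuracy_vs_eyes()` compares the binarized trace against eyes-open/closed
scoring: the trace is thresholded (0.3–0.7 in 0.1 steps, since 0.5 need not
be the behavioural boundary; values at the threshold count as conscious),
aggregated to one prediction per 5-min scoring epoch by sample majority,
and scored as (TP+TN)/(TP+TN+FP+FN) against O = 1, C = 0. Epochs scored
O/C (intermittent) or unavailable are excluded. The temporal alignment unit
is a choice: scoring exists per 5-min epoch while the trace ticks at 1 Hz,
so the epoch-majority rule is the default and a per-sample comparison is
available via `per_sample = TRUE`.

## The synthetic generator

Clinical recordings of this population are not redistributable, so the
package ships a seeded generator (`generate_recording()`,
`generate_eyes_scoring()`) that emulates exactly the statistical structure
the method assumes. Each state is a weighted sum of unit-variance
band-limited noise components (δ 0.5–4, θ 4–8, α 8–12, β 12–30 Hz) plus a
broadband 0.5–45 Hz component; band components are realized by FFT noise
shaping (zeroing out-of-band bins of white noise), which gives exact band
limits without filter transients or instability. θ coupling is a shared
θ-band source added to every channel with a channel-specific delay of 1–10
samples — pure zero-lag sharing would have zero imaginary coherency (it
would look like volume conduction) and defeat the iCOH pathway. State
transitions are instantaneous, giving a crisp ground truth; eyes epochs
are labeled by the majority state within the epoch (`O/C` only for exact
ties) and can be degraded to NA at a configurable rate.

Default state parameters (amplitude weights): conscious δ 0.5, θ 0.8,
α 0.4, β 0.6, broadband 0.4, coupling 0.6; unconscious δ 1.0, θ 0.3,
α 0.5, β 0.15, broadband 0.1, coupling 0.1. These were chosen once so that
each hypothesized contrast holds with clear separation: conscious θ and β
relative powers several-fold higher, SEF95 ≈ 28 Hz versus ≈ 10 Hz,
and a four-fold broadband (randomness) ratio driving ERR and LZC.

What the generator does *not* emulate: 1/f spectral shape, artifacts,
nonstationarity within a state, sleep architecture, and realistic
electrode geometry. Passing the end-to-end recovery test therefore shows
the pipeline is internally consistent — it recovers states that differ in
exactly the hypothesized directions — not that the hypotheses hold in
clinical EEG.

A caveat worth knowing: the *measured* θ-connectivity baselines are
dominated by estimator bias at these window lengths (15 Welch sub-windows;
≈1500 symbols). The bias of |Im(coherency)| and of empirical mutual
information grows as the effective number of independent sub-windows or
symbols shrinks, which happens for the strongly autocorrelated, δ-dominated
unconscious signals. Under the default parameters the conscious/unconscious
contrast in measured iCOH and wSMI is therefore weak and can even reverse,
even though the generative coupling is higher in conscious segments;
increasing the coupling strength at fixed state parameters does increase
both measures, which is the monotonicity property the tests check. The
clustering is robust to this because the five spectral/complexity features
separate strongly and the conscious label needs only a majority of
coordinates.

## Numerical choices and degenerate inputs

* PSD sums are discrete grid sums; in-band means bin center within limits,
  inclusive. On an idealized flat spectrum sampled at 0.025 Hz this gives
  θ relative power 0.0894 versus the continuous 4/45 ≈ 0.0889 — the
  inclusive-endpoint discretization, not an estimator property.
* SEF95 of a flat spectrum on that grid is exactly 0.95 normalized.
* Zero-power windows: relative power and SEF are NaN (flagged), never an
  error; all-zero signals binarize to all-zero bits (LZ76 count 2 for any
  constant sequence longer than 1).
* ERR returns NaN when SD2 = 0 (constant or perfectly anti-periodic
  windows).
* FCM's `J_m` is nonincreasing and the GMM log-likelihood nondecreasing by
  construction; both traces are recorded per iteration and asserted in the
  tests.
* All stochastic stages (generator, FCM restarts, GMM starts) consume
  explicit integer seeds through `withr::with_seed`, so identical configs
  reproduce byte-identical outputs without touching the session RNG.

## Test problem sizes

The test-suite sizes were chosen to exercise every claim at desk scale:
unit tests run the generator at 200 Hz with 4 channels and tens of seconds;
bound sweeps use 1000 seeded 512-sample pairs; the independence limit uses
10^5 symbols; and the end-to-end recovery test runs the full default
conditions — 500 Hz, 6 channels, ten alternating 5-min states (50 min of
signal) — and requires ≥ 90% epoch agreement at threshold 0.5, the
package's own design target for a generator configured with well-separated
states.

## Limitations

* The θ-band Welch grid at the stated window length is coarse (one or two
  bins); iCOH consequently averages very few bins.
* wSMI's weight convention makes identical inputs score 0 by design; it
  measures *non-trivial* dependence.
* Min–max normalization is sensitive to outlier windows; with no artifact
  rejection, a single extreme window compresses the remaining range.
* The conscious/unconscious labeling presumes the recording actually
  contains both states; a recording confined to one state still yields two
  clusters, and the trace then reflects within-state variability rather
  than consciousness.
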