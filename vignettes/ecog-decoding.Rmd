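---
title: "Decoding 3-D hand trajectories from ECoG band power: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding 3-D hand trajectories from ECoG band power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Electrocorticographic (ECoG) grids over primary motor cortex record field
potentials whose band-limited power co-varies with arm movement. Given a
multichannel recording and a synchronized 3-D hand position (wrist marker),
the offline decoding question is: how well can a linear model read the hand
trajectory from the recent history of band-envelope features, which
electrodes carry that information, and which frequency bands?

Because no public recording of this kind is available at the scale the
pipeline expects, the package ships a synthetic-data generator with planted
ground truth. Every claim the test suite makes is therefore a claim about
*recoverability*: if coupling of a known form is planted at known
electrodes and bands, the pipeline must find it, and must find nothing when
nothing is planted.

## Feature model

Raw potentials (channels × samples, 500 Hz) are processed as:

1. **Common average reference.** Subtract the per-sample mean across
   channels; removes reference drift and far-field common-mode signal.
2. **Band-pass filtering** into nine physiological bands: δ 1.5–4, θ 4–8,
   α 8–14, β1 14–20, β2 20–30, γ1 30–50, γ2 50–90, γ3 90–120, γ4 120–150 Hz.
   The filter is a 4th-order Butterworth applied forward–backward
   (zero-phase) with reflective edge padding. Whether a causal or
   zero-phase filter is the "right" reading of standard practice is
   genuinely open; zero-phase was chosen because it preserves the temporal
   alignment between envelopes and kinematics that the lagged decoder
   relies on, and the decoder's 30–600 ms lags dominate any residual
   alignment question. At 500 Hz the δ band's 1.5 Hz edge is numerically
   delicate; the design was validated by checking stability and in-band
   gain of the filtered output directly (the double-pass `(b, a)` form is
   stable here; see the band-pass tests).
3. **Envelope**: rectification followed by convolution with a truncated
   unit-area Gaussian (total width 0.1 s, σ = 0.04 s). Unit area makes the
   DC gain exactly 1, so constant signals pass unchanged.
4. **Causal sliding z-score**: each envelope sample is standardized by the
   mean and SD of the preceding 2 s, taken over the half-open window
   [t − 2 s, t) — strictly before t, so features are causal by
   construction. The first 2 s of every session have no complete window
   and are excluded from all fitting and evaluation (`valid_from`).
   Windows with numerically zero spread are guarded by a floor of
   `max(1e-4 × channel SD, tiny)`; a constant channel yields 0, never
   NaN/Inf.

The result is the feature tensor S(i, j, t) (channel × band × time).

## Decoder

Position on each axis is modeled as a linear function of the feature
tensor over the 0.6 s preceding the prediction time: 20 lags spaced 30 ms,
i.e. lags k·30 ms for k = 1..20, excluding lag 0 — "before t" is read
strictly, and 20 × 30 ms exactly tiles (0, 0.6]. One design row is built
per 30 ms stride by default (fitting at the full 500 Hz adds ~15× more
rows that are nearly duplicates of their neighbors; a finer stride can be
configured).

The decoder is multi-response PLS (PLS2): factors are extracted
sequentially, each weight vector being the dominant left singular vector
of the current cross-covariance X'Y — the fixed point of the classical
NIPALS inner iteration — with deflation carried on the cross-covariance
(kernel formulation). This is algebraically identical to NIPALS PLS2 with
joint deflation, but it is deterministic (no iterative convergence
tolerance) and runs off crossproduct matrices. Since centering and column
selection commute, every channel- or band-restricted model is fitted from
a submatrix of one cached crossproduct, which is what makes exhaustive
single-electrode ranking cheap. X is centered but not rescaled (features
are already dimensionless z-scores); Y is centered only, keeping its
physical units. The test suite verifies equality with ordinary least
squares on full-rank problems and with an independent NIPALS
implementation (mixOmics) in the rank-deficient regime.

### Choosing the number of latent variables

Ten-fold cross-validation on the training segment, with **contiguous
temporal folds** — never shuffled: rows are an autocorrelated time series
and shuffled folds leak neighboring samples between train and validation,
inflating accuracy. For each candidate count the predictive error sum of
squares (PRESS) over held-out folds is accumulated; the selected count is
the smallest one within 1% of the PRESS minimum (the start of the
plateau), capped at 20. A fixed count can be supplied instead.

One addition proved necessary: the curve also records the PRESS of the
intercept-only predictor (the training mean), and if no latent count beats
that baseline by more than one standard error of the paired per-fold PRESS
difference, **zero** latent variables are selected and the decoder is the
mean. Without this guard, PLS fits spurious structure on data with no
planted coupling: slow envelope fluctuations stay phase-coherent across a
session, so a spurious factor can show a small, unreliable CV gain inside
the training segment and still generalize nowhere — held-out R² near −0.2
rather than 0 at the session lengths used here. The one-SE rule is the
standard parsimony device for exactly this situation; in our null
simulations the best factor's gain is ≤ 0.6 SE while planted-coupling
sessions exceed 20 SE, so the guard never bites on real signal.

## Evaluation

The session is split contiguously: the first 500 s (by default) for
training, the following 200 s for testing; nothing is shuffled. Reported
R² is the coefficient of determination 1 − SS_res/SS_tot per axis, about
the test segment's own mean, averaged over x, y, z. It is *not* a squared
correlation: out-of-sample values can be negative and are reported as-is.

## Electrode selection

Two procedures, both refitting the full decoder per channel subset on the
common split:

- **Location-based**: nested groups built by taking whole grid columns in
  order of proximity to the central sulcus (column 1 first) and filling
  within a column from the lateral end inward (row 1 being most medial).
  The within-column fill order is not dictated by anything physical in the
  synthetic setting; lateral-first is the default and the choice is an
  exposed argument, not a hidden constant. Whole-column and whole-row
  partitions are evaluated the same way.
- **Performance-based**: every electrode is scored by decoding with that
  electrode alone (same split, same latent-count policy as the full model,
  capped by the restricted design's rank); electrodes are then added in
  rank order and the decoder refit at each requested size. Ties in the
  ranking break by ascending channel id. Single-electrode models are
  evaluated on the held-out segment, not by CV on training data — the
  held-out estimate is the quantity the ranking is later judged by.

## Band analysis

For a fitted model, the contribution of band j to axis p is
Σ_{i,k} |w_p(i, j, k)| / Σ_{i,j,k} |w_p(i, j, k)|, in percent; per axis the
contributions sum to 100 by construction. Contributions are computed per
axis (three panels) and also summarized as their mean. Per-band decoding
refits the model restricted to one band at a time. A comparison harness
runs the same pipeline under the nine physiological bands and under a
uniform partition into 10-Hz-wide bands (0–150 Hz; the lowest edge is
raised to 0.5 Hz to keep the band-pass design well-posed). Differences
between bands are reported as R² tables without formal significance
testing — the inferential ANOVA in this setting would test properties of a
particular animal's recordings, not of the method.

## Synthetic data: what it emulates, and what it does not

A session emulates: ~700 s of continuous recording; a 4×8 grid of 32
channels (column-major ids, column 1 nearest the central sulcus) or any
other rectangular grid; reach-grasp-pull-release cycles of ~5 s with 10%
per-cycle amplitude and period jitter (clipped at ±2× so trajectories are
bounded); per-band carriers synthesized as band-limited Gaussian noise in
the frequency domain (power confined to the band); envelopes
1 + w·√snr·σ_env·drive(t − lag) + σ_env·(slow noise), floored at a small
positive value; broadband white noise; and a shared low-frequency
common-mode component (so common-average referencing does real work). The
kinematic drive is the standardized sum of the three standardized position
coordinates and the smoothed hand speed — one fixed, documented linear
functional of the trajectory; any drive linearly recoverable by the lagged
decoder would serve. The default coupling lag is 0.09 s, inside the
decoder's 0.6-s window; the default SNR (coupled-to-noise envelope
variance ratio) is 10.

Deliberately absent: biophysical cortical dynamics, spikes, cross-channel
spatial correlation beyond the common mode, line noise, artifacts,
non-stationarities, and any nonlinearity between kinematics and envelope
beyond the positivity floor. Trial-to-trial kinematic variability is
stylized (independent Gaussian jitter per cycle), not calibrated to any
animal. Passing recovery tests therefore demonstrates that the *pipeline*
is sound — that it finds planted structure and rejects its absence — not
that real cortex behaves like the generator.

## Problem sizes and numerical choices

Unit tests run on 60-s, 8-channel sessions; recovery and null property
checks on 150-s, 32-channel sessions (100 s train / 45 s test) at the full
500-Hz analysis rate; the acceptance script runs one full-length 700-s,
32-channel session (500 s train / 200 s test) plus a 150-s zero-coupling
control. These sizes are the package's own desk-scale choices; every
stage's parameters (rates, band edges, window lengths, lag structure)
stay at their full-scale values throughout, so the small sessions differ
from the big one only in duration.

Other numerical details: filters are designed per band and applied with
reflective padding of 3 cycles of the band's low edge; the Gaussian
smoothing kernel is truncated at its stated width and renormalized;
factor extraction stops with an error (never silently) if the residual
cross-covariance vanishes before the requested count; determinism is
end-to-end — generators save and restore the global RNG state, and
rerunning any analysis with the same config and seed reproduces every
output byte.

## Known limitations

- The 0-latent fallback makes the null case honest but means a session
  with genuinely marginal coupling may be reported as undecodable; raise
  `max_latent`/lower `plateau_tol` and inspect the CV curve if that is in
  question.
- Contiguous single train/test splits estimate out-of-sample accuracy with
  substantial variance at short session lengths; the per-seed spread seen
  in the stochastic tests reflects that, and short test segments can make
  chance-level R² mildly negative (segment means differ).
- The generator's scalar drive makes the three output axes share one
  latent kinematic source; decoders that exploit richer cross-axis
  structure are not distinguishable from PLS on these data.
- Bands are processed independently; cross-band phase structure (e.g.
  phase-amplitude coupling) is neither generated nor modeled.
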