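# ecogpls

Offline decoding of continuous 3-D hand trajectories from multichannel
electrocorticography (ECoG), for researchers studying motor
brain–machine interfaces who want a tested, reproducible reference
pipeline: band-envelope feature extraction, a lagged partial-least-squares
decoder with cross-validated model selection, two electrode-selection
procedures, and frequency-band contribution analysis. Because suitable
recordings are rarely shareable, the package includes a synthetic-data
generator with planted ground truth, so every stage is verifiable by
parameter-recovery tests rather than by eyeballing.

## The model

Raw potentials are common-average referenced, band-pass filtered into nine
physiological bands (δ 1.5–4, θ 4–8, α 8–14, β1 14–20, β2 20–30, γ1 30–50,
γ2 50–90, γ3 90–120, γ4 120–150 Hz; zero-phase 4th-order Butterworth in
second-order sections), rectified, smoothed with a 0.1-s Gaussian
(σ = 0.04 s), and z-scored causally against the preceding 2 s, yielding the
feature tensor S(i, j, t) for channel i and band j.

The decoder predicts each position coordinate p ∈ {x, y, z} at time t from
the 0.6 s of features before t:

    p̂(t) = Σ_i Σ_j Σ_{k=1..20} w_p(i, j, k) · S(i, j, t − k·Δt) + a_p ,  Δt = 30 ms

The weights come from multi-response partial least squares (PLS2,
NIPALS-equivalent kernel implementation): latent factors maximizing
X–Y covariance are extracted sequentially; the number of latent variables
is chosen from the ten-fold cross-validated PRESS curve (smallest count
within 1% of the minimum, capped at 20, with an intercept-only fallback
when no factor beats the mean predictor). Accuracy is the per-axis
coefficient of determination R² = 1 − SS_res/SS_tot on a held-out
contiguous test segment.

Electrode subsets are chosen two ways: *location-based* (nested groups
expanding column-by-column from the central sulcus) and
*performance-based* (rank electrodes by single-electrode decoding R², then
grow the set in rank order). Band importance is measured both by each
band's share of the decoder's absolute weights (contributions summing to
100% per axis) and by decoding with one band at a time.

## Worked example

Simulate a small session — 8 electrodes on a 4×2 grid, 60 s at 500 Hz,
with channels 1–3 carrying envelope coupling to the hand kinematics in the
γ3/γ4/δ bands — then decode and rank the electrodes:

```r
library(ecogpls)

ds <- make_dataset(list(duration_s = 60, fs = 500, n_rows = 4, n_cols = 2,
                        truth = ground_truth(informative_channels = 1:3, snr = 10),
                        seed = 7))
ctx <- prepare_decoding(ds, decoding_config(train_s = 40, test_s = 15))
fit <- decode_full(ctx)
fit$n_latent
fit$r2
head(single_channel_scores(ctx, n_latent = fit$n_latent), 4)
band_contribution(fit$model)[c("band", "mean")]
```

```
[1] 1
$per_axis
        x         y         z
0.5720051 0.6934036 0.7893166

$mean
[1] 0.6849084

  channel      r2_x      r2_y      r2_z   r2_mean
1       2 0.5917291 0.6854489 0.7693377 0.6821719
2       3 0.5056824 0.6098724 0.7161498 0.6105682
3       1 0.4429155 0.6000319 0.6900808 0.5776761
4       8 0.1873609 0.1996786 0.2117425 0.1995940
    band      mean
1  delta 16.613371
2  theta  5.117860
...
8 gamma3 31.079241
9 gamma4 26.354986
```

The three planted electrodes head the ranking, the held-out mean R² is
0.68 from a single latent variable (the planted drive is one-dimensional,
and PRESS selection knows it), and the planted bands — γ3, γ4, δ — take
the three largest weight shares. Numbers are deterministic for the shown
seed.

## The full analysis

The `analysis/` scripts run the study end to end on a simulated session
and write their tables under `results/` (the dataset container itself goes
under `scratch/`):

```sh
Rscript analysis/01_simulate.R            # simulate + write the session
Rscript analysis/02_decode.R              # PRESS curve, latent count, held-out R²
Rscript analysis/03_electrode_selection.R # both selection methods, heatmap
Rscript analysis/04_band_analysis.R       # contributions, per-band R², band-set comparison
```

`run_full_analysis()` does the same in one call and returns a structured
report; `write_report()` serializes it to JSON + CSV.

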