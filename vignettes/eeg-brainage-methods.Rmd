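---
title: "Brain age from EEG: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age from EEG: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eegbrainage)
```

## The problem

The brain age gap (BrainAGE) is the difference between the age a model
predicts from a brain measurement and a person's chronological age. Most
work estimates it from structural MRI; this package implements an
EEG-based pipeline: resting-state EEG is reduced to a large set of
interpretable per-channel, per-band features, redundant features are
removed, chronological age is predicted with a nested cross-validated
stack ensemble of standard regressors, and the outer-fold predictions
yield one unbiased BrainAGE value per subject together with fold-robust
feature importance and partial-dependence interpretation.

The design premise is interpretability over raw accuracy: every feature
is a named, well-understood quantity (`spectral.wiener_entropy.beta.TP9`
reads as "spectral flatness, beta band, channel TP9"), so the model's
drivers can be mapped back to channels, bands and feature families.

## Preprocessing

Recordings (EDF or BrainVision) are resampled to 250 Hz (4 ms
resolution), band-pass filtered to 1–70 Hz, and band-stop filtered with
1 Hz-wide notches at the harmonics of a 19.5 Hz slice-selection
frequency, at 60 Hz, and at 26 Hz (artifact frequencies typical of EEG
recorded during fMRI; notches at or above Nyquist are skipped). A
bipolar montage (anode − cathode derivations; a 31-pair longitudinal
"double banana"-style default ships with the package) and segmentation
into 60 s epochs with 50 % overlap follow. The epoch count is
`floor((duration − 60)/30) + 1`; trailing partial epochs are discarded
rather than padded, because averaging features across unequal-length
epochs would bias them.

Numerical choices worth knowing:

* **All filters are zero-phase frequency-domain filters** with
  Butterworth-shaped magnitude responses (band-pass effective order 10,
  notches effective order 4, quoted as two-pass equivalents). Zero phase
  preserves the relative timing between channels, which the connectivity
  features depend on. A conventional IIR band-pass applied at a 1 Hz
  corner on multi-kHz input is numerically fragile and, at order 4,
  leaves 25 % of an 80 Hz tone — the frequency-sampled response meets a
  ≥ 20 dB stop-band requirement cleanly and is exactly idempotent-friendly
  (repeated application changes band-interior content by < 0.1 %).
* **Resampling is spectral (sinc) resampling**: the Fourier spectrum is
  truncated at the new Nyquist frequency and inverse-transformed at the
  new length. This is exact band-limited interpolation with inherent
  anti-aliasing and unit passband gain. (The polyphase resampler in the
  available `signal` package was measured to distort passband amplitude
  by ~15 %, which would corrupt every amplitude-domain feature.)
* Non-finite samples are an ingestion error, never imputed.

## The feature set

Features are computed per epoch, per channel, per band — delta 0.5–4,
theta 4–7, alpha 7–13, beta 13–30 Hz, with W = 0.5–30 Hz as the
whole-range reference — and averaged across epochs. Band membership on
the frequency grid is half-open `[lo, hi)`, so the four bands partition
W exactly and relative powers sum to one. With N = 31 channels the
default layout is:

| domain | features | count |
|---|---|---|
| amplitude | total power, sd, skewness, kurtosis (raw), envelope mean, envelope sd | 6 × 4 × 31 = 744 |
| range-EEG | mean, median, p5, p95, sd, cv, quantile symmetry of 2 s peak-to-peak windows | 7 × 4 × 31 = 868 |
| spectral | band power, relative power, Wiener entropy (flatness), normalised Shannon entropy, 95 % spectral edge frequency, short-time spectral difference | 6 × 4 × 31 = 744 |
| connectivity | brain symmetry index, median/lag of max envelope rank cross-correlation, mean coherence, median peak-coherence frequency | 5 × 4 = 20 |
| fractal | Higuchi fractal dimension (kmax = 6, unfiltered signal) | 31 |

Details and conventions:

* The amplitude list nominally contains seven statistics, but the
  band-filtered signal is zero-mean by construction, so the raw mean is
  dropped and six are emitted — this is what makes the 6 × 4 × 31 column
  count come out exactly.
* The **envelope** is the squared magnitude of the analytic signal,
  `|x + iH(x)|²`, computed in the frequency domain.
* The **Welch PSD** uses 2 s Hamming windows with 50 % overlap and
  density scaling (integrated PSD ≈ variance). Spectral features are
  evaluated on the unfiltered epoch's PSD restricted to each band,
  which is equivalent to filtering first up to filter rolloff inside the
  band. The short-time spectral difference is the mean squared change
  between consecutive windowed amplitude spectra over in-band bins.
* The **brain symmetry index** averages, over in-band frequencies, the
  absolute normalised difference between hemisphere-mean spectra,
  `|(P_L − P_R)/(P_L + P_R)|` — 0 for symmetric hemispheres, 1 when all
  power sits on one side.
* The **envelope cross-correlation** rank-transforms each envelope once
  over the epoch and correlates the rank series at every integer-sample
  lag within ±200 ms (Pearson on ranks; exactly Spearman at lag zero).
  Re-ranking every overlap window at every lag would multiply the cost
  of the whole pipeline several-fold for a near-identical statistic.
  Positive lag means the right-hemisphere channel leads. Medians across
  the 13 homologous left/right derived-channel pairs are reported.
* The rEEG "measure of symmetry" is quantile skewness,
  `((p95 − median) − (median − p5))/(p95 − p5)`; the cv is sd/mean with
  a 0-with-warning convention for degenerate input, and moments are
  population moments (kurtosis is raw, Gaussian = 3).
* **Higuchi fractal dimension** fits −slope of log L(k) on log k for
  k = 1…6 by OLS; estimates are clipped to [1, 2] with a warning and a
  constant series returns 1 by convention.

## Feature reduction

Reduction is response-blind and happens once on the full table: first a
near-zero-variance filter (constant columns, or frequency ratio > 95/5
with < 10 % unique values), then iterative removal of correlated pairs —
repeatedly take the remaining pair with the highest |Pearson r|, and
while it is ≥ 0.9 drop the member with the larger mean absolute
correlation against all remaining features (ties go to the earlier
column, making the output deterministic). Because the correlation matrix
never changes, this is implemented as a single pass over the pre-sorted
candidate pairs with incrementally maintained row sums. The surviving
set provably contains no pair at or above the cutoff. Being
response-blind is what makes fitting it outside the cross-validation
folds defensible; supervised selection would have to run inside every
fold.

## Modeling

Five base regressors — elastic net (`glmnet`), radial-kernel SVR and
polynomial-kernel Gaussian process regression (`kernlab`), random forest
(`ranger`), gradient-boosted trees (`xgboost`) — are tuned per outer
fold by inner cross-validation (defaults K_I = 10 folds × R = 5
repeats), scored by RMSE, with the **one-standard-error rule**: the most
parsimonious grid point whose mean RMSE is within one standard error of
the minimum wins. Parsimony orderings are declared per method (heavier
shrinkage first for the elastic net, smaller C first for SVR, smaller
mtry first for the forest, shallower/fewer rounds first for boosting,
lower degree first for the GP). Feature standardisation (z-score, fit on
the outer-training fold only) is applied for the penalised and kernel
methods; tree methods see raw features. The SVR kernel width uses a
deterministic median-distance heuristic so results are bit-reproducible.

The **stack ensemble** is a general linear model (intercept + one weight
per method) trained on the pooled held-out inner-resample predictions at
each method's selected hyperparameters — the meta-model never sees outer
test subjects. The weights carry a ridge penalty chosen by K_Ens-fold
cross-validation over a path whose light end is effectively ordinary
least squares: with informative base models the fit is OLS-like, while
on uninformative (or collinear) predictions the cross-validation drives
the weights toward a calibrated intercept-only model. This matters for
honesty under the null — an unpenalised five-coefficient meta-fit
carries a small but systematic negative R² bias (≈ −0.05 at n = 200)
on permuted-label data, which regularised stacking removes without
measurably affecting performance when signal is present. Outer test
predictions are the weighted combination of
the refitted base models; concatenating the outer folds yields exactly
one prediction per subject, and `BrainAGE = predicted − chronological`.
R² is reported as `1 − SS_resid/SS_total` of the predictions themselves,
not of a refitted regression line, alongside MAE, RMSE and Pearson r,
pooled and per fold (mean ± sd).

One master seed drives everything: fold assignments, per-fit seeds and
subsampling all derive child seeds through a deterministic
multiplicative scramble, so a configuration + seed reproduces an
`ncv_result` exactly.

A `fast = TRUE` preset (K_O = K_I = 5, R = 1, near-single-point grids,
150-tree forests, 60-round boosting) is the package's documented
reduced configuration for desk-scale synthetic cohorts and for the
acceptance checks; the full preset mirrors the conventional 10 × 10 × 5
layout.

## Interpretation

Per fold, each base model contributes an importance vector — |coefficients|
for the elastic net, impurity for the forest, gain for boosting, and
permutation importance (MSE increase on a deterministic training
subsample, one permutation) for the kernel methods, whose raw scales are
incomparable and are therefore normalised to sum 1 per model before
being combined with the normalised absolute stack weights. Each fold's
combined vector is rescaled to sum exactly 100, then averaged across
folds; features are annotated with their marginal Pearson correlation
with age. Partial-dependence curves sweep one feature over 25
quantile-spaced points of the fold's observed range while averaging the
stack prediction over the fold's training rows; the consistency
statistic is the mean pairwise Pearson correlation between fold curves
on their common range. `spatial_importance()` parses the structured
feature names into channel × band grids per domain and into domain and
band percentage shares; a channel/value TSV can feed any topographic
plotting tool, so no plotting dependency is load-bearing.

## The synthetic cohort generator

Real resting-state EEG with age labels at cohort scale is not shippable,
so validation uses a generator whose defaults are fixed study
conditions, not tuning knobs: 31 bipolar-derived channels at 250 Hz,
ages uniform on 18–58 y, and per-band sinusoidal oscillators whose
amplitude and peak frequency are affine in age — alpha amplitude
28 − 0.25·age µV and peak frequency 11 − 0.025·age Hz (amplitude decline
and gradual alpha slowing are the most replicated resting-state aging
effects), theta declining mildly, delta/beta drifting slightly up.
Subject-level lognormal scatter (sd 0.25) models biological variability
that averaging channels cannot remove, per-channel scatter is 0.08,
the left hemisphere is scaled by 1.05 and the right by 0.95
(asymmetry 0.1, giving the symmetry index something to measure), slow
amplitude modulation (depth 0.2 at 0.1 Hz) gives envelopes structure,
and 1/f background noise is added at SNR 2 — defined as the
cohort-reference oscillator variance (mid-age amplitudes, no scatter)
over in-band noise variance, so the noise level is identical for every
subject. That reference matters: scaling noise to each subject's own
oscillators would make noise amplitude track alpha amplitude and leak a
planted "alpha-only" age effect into every frequency band. An
`alpha_only_band_effects()` preset confines the age signal to alpha
amplitude (slope −0.3, scatter 0.15, used with SNR 2.5) for
planted-structure recovery experiments. Even so, a change in oscillator
amplitude necessarily expresses in several feature domains at once —
band-filtered amplitude sd, range-EEG sd and (relative to fixed noise)
fractal dimension are near-perfectly correlated proxies of it, and the
correlation-reduction step keeps one arbitrary representative of that
cluster. Recovery experiments therefore assert on the planted structure
in the spatial aggregation — the top-ranked feature being alpha-band,
alpha dominating the band-level importance shares, and the alpha cells
of the spectral-domain channel × band grid dominating that grid — rather
than on which cluster proxy happens to rank first.

The default recording length is 480 s (8 min); the test suite and the
acceptance script use the 120 s short mode (3 epochs — the epoch
formula, not the duration, is what all downstream code depends on) with
cohorts of 200 subjects for the hygiene/stacking checks and 100 for the
interpretation-recovery check, sizes at which the full pipeline runs in
minutes on one CPU.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: non-sinusoidal and non-stationary
oscillatory dynamics, real artifact topographies (ocular, muscle,
gradient, cardioballistic), volume-conduction correlation structure
between channels, and any nonlinear age dependence. Recovery results on
synthetic cohorts validate the machinery (no leakage, planted signal
found, importance localised correctly), not field-strength effect sizes.

## Known limitations

* Kernel-method importance rests on a one-permutation, subsampled
  permutation scheme; it is cheap and fold-averaged, but noisier than
  the native extractors.
* The frequency-domain filters are circular; for epoch-length signals
  the wrap-around affects only the outermost samples and none of the
  windowed statistics meaningfully, but single-window features on very
  short signals would see edge effects.
* Reduction outside the folds is justified by response-blindness, but a
  stricter within-fold rerun is a one-line change (`reduce_features` on
  each training fold) at ~K_O times the cost.
* The EDF writer emits 16-bit, 1 s records and requires an integral
  sampling rate; the BrainVision reader supports float32/int16 binary
  data only (no ASCII).
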