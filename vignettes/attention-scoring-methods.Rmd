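---
title: "Methods: frontal-EEG attention scoring and trial simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frontal-EEG attention scoring and trial simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(basm)
```

## The problem and the model

Children with attention-deficit/hyperactivity disorder tend to show a
characteristic resting-EEG signature over frontal sites: elevated
slow-wave (theta, 4–8 Hz) and reduced fast-wave (beta, 13–30 Hz)
activity during inattention, with the balance shifting toward beta under
focused attention. A neurofeedback training game exploits this by
deriving a per-block attention score from two frontal dry electrodes
(Fp1, Fp2) and feeding it back as avatar speed, so that sustaining
attention is what moves the game forward.

The scoring model fitted by `fit_attention_model()` is deliberately
simple and subject-specific:

1. **Features.** Each 2-s block of clean signal yields a 24-vector of
   band powers: 8 contiguous bands over 4–30 Hz for each of Fp1, Fp2 and
   the virtual differential channel Fp1 − Fp2. Band power is the sum of
   one-sided FFT power over the band's bins; block values are averaged
   per epoch and log₁₀-transformed.
2. **Selection.** Features are ranked by the plug-in mutual information
   (in bits, equal-frequency binning) between the feature and the
   attentive/relaxed calibration label; the top *k* are kept. MI is used
   rather than a univariate t-statistic because it is invariant to
   monotone feature transforms and captures non-linear separations.
3. **Regression.** A ridge-penalised linear regression of the ±1 state
   coding on the standardized selected features yields the raw score
   (unbounded; higher = more attentive). Ridge keeps the fit stable at
   calibration sizes of a few dozen epochs.
4. **Display transform.** The 0–100 score shown to the trainee is
   `100 · logistic((raw − center)/scale)`, with `center` the midpoint of
   the calibration class means and `scale` chosen so the mean attentive
   epoch maps to 75 and the mean relaxed epoch to 25. The display score
   is monotone in the raw score and saturates gracefully; the raw score
   itself is *not* clamped, which is why population summaries of raw
   scores can fall outside [0, 100].

Assumptions worth stating: state-dependent spectra are stationary within
an epoch; the two-class calibration contrast (task-engaged vs resting)
spans the attention axis the game later traverses; and a linear score in
log band powers suffices — the model makes no attempt at non-linear
classifiers by design.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `block_len` | 2 | s | one block = 256 samples at 128 Hz = the FFT length |
| `fs` (generator) | 128 | Hz | unpublished for the device; chosen so a 2-s block is exactly 256 samples |
| filter bank | 8 × 3.25 Hz | Hz | count and 4–30 Hz coverage are fixed; equal widths are the neutral choice when the device's edges are unpublished. `classical_filter_bank()` offers theta/alpha/beta-aligned edges |
| FFT window | rectangular | — | only the FFT length is specified for the device; Hann is available |
| `k` | 6 | features | unpublished; 6 of 24 keeps the ridge fit well-determined at ~40 epochs |
| `n_bins` (MI) | 8 | bins | equal-frequency; coarse enough to limit plug-in bias at calibration sizes |
| `ridge` | 1 | — | stabilises coefficients at n ≈ 40 without materially biasing the separation |
| `rail` | 512 | µV | saturation threshold; ADC range unpublished, configurable |
| `flat_eps`, `flat_window` | 0.1, 1 | µV, s | a disconnected dry electrode reads as near-constant; 1 s windows localise the defect |
| `guard` | 2 | s | exclusion around an abnormality; applied symmetrically (the direction is unstated in the protocol description, and symmetric is the conservative reading) |
| `smoothing` | 3 | blocks | 6 s trailing average gives playable score dynamics; the deployed game's smoothing is unpublished |
| `v_max` | 2 | units/s | arbitrary track scale; speed is proportional to score through the origin |

## What the synthetic data emulates — and what it does not

`simulate_eeg()` realises each band oscillation as brick-wall band-passed
white noise scaled to a target RMS (so band power spreads over the band
rather than sitting in one FFT bin), adds 1/f pink background noise, and
superimposes 300-ms half-sine blink transients *identically on both
channels* — frontal ocular artifacts are common-mode, which is precisely
what the virtual differential channel exploits. The default
attentive/inattentive profile pair has theta/beta amplitude ratios 0.5
vs 4 with identical alpha, background and blink parameters, so only the
discriminative bands differ.

`simulate_trial()` draws baseline IA/HI subscores from truncated normals
on [0, 27] (means 17.7/15.6, SDs 5.0/3.9 — the cohort the defaults
emulate), generates follow-up scores as
`baseline + effect_slope × baseline + noise` (half effect at the
mid-treatment week-4 visit), clamps to the legal range, sets
COM = IA + HI, applies configurable dropout hazards (defaults 5% before
week 4, 10% before week 8, matching a 17/20 completion), and couples the
week-20 attention-score change to the combined-score change with a
target correlation (default −0.6). An optional `change_intercept`
(default 0) adds a baseline-independent change component for cohorts
whose mean change is smaller than the slope alone would imply.

Passing tests on these generators shows the pipeline recovers structure
*of the kind assumed*: band-limited stationary contrasts, common-mode
artifacts, linear baseline-change coupling. Real EEG is nonstationary,
has muscle and movement artifacts that are not common-mode, and real
trial data have informative missingness — none of which the generators
emulate, so green tests here do not certify performance on real
recordings.

## Numerical choices

- **Spectrum normalisation.** `block_spectrum()` returns one-sided power
  `|X_k|²/N²` with interior-bin doubling, so the spectrum sums to the
  block mean square (Parseval); the tests assert this to 1e-6 relative
  on random blocks and 1e-9 for pure tones. Hann windowing is
  compensated by its mean-square gain.
- **Half-open conventions.** Bands are `[low, high)` so contiguous bands
  never double-count a bin; mask intervals and blocks are half-open in
  time; block tiling is anchored at the recording start and a trailing
  partial block is dropped.
- **Flatline detection.** Rolling variance via cumulative sums with
  negative values clipped to zero; the rule (window sd < `flat_eps`) is
  validated against a brute-force per-window scan in the tests.
- **MI ties and degeneracy.** Equal-frequency bin edges that collapse
  (ties) reduce the effective bin count; a constant feature returns
  MI = 0. Selection breaks exact MI ties by ascending feature index so
  refits are reproducible.
- **Degenerate statistics.** Paired differences with (numerically) zero
  variance return a flagged result with p = 1 instead of erroring;
  standardizer SDs below 1e-12 are replaced by 1 (such features carry no
  signal and are never selected).
- **Logistic anchoring.** `scale = (m_att − m_rel)/(2 ln 3)` places the
  class means at 75/25; a floor of 1e-6 guards a (pathological)
  non-positive separation.
- **Resampling.** If `fs ≠ 128`, blocks are linearly resampled to 256
  samples so the 256-point FFT length is invariant.
- **Determinism.** Every generator takes a `seed` and restores the
  caller's RNG stream; identical seeds give bit-identical output.

## Open design decisions

The deployed device's regression target, feature count, MI estimator,
band edges, window, sampling rate and ADC range are all unpublished.
Each is surfaced as a configurable argument with the defaults above, and
the acceptance checks are written as *property-based* recoveries
(parameter recovery, discrimination, conservation laws) rather than
numeric matches to cohort values that depend on unavailable
individual-level data. The week-24-vs-baseline analysis set is ambiguous
in the source cohort (LOCF n = 19 vs per-visit n = 17); `mean_change()`
operates on whichever table it is given, so both readings are available
and neither is asserted.

The multiple-imputation robustness check is an interface stub
(`impute_missing(method = "mi")` errors informatively): it is an
off-the-shelf sensitivity analysis, not part of the method, and the
primary analysis is LOCF.

## Problem sizes

The test suite and acceptance script use calibrations of 40 epochs of
10 s at 128 Hz, sessions of up to 5 minutes, trial cohorts of up to 200
subjects, and 100-cohort replications for sign-recovery rates; the full
suite runs in well under a minute. These sizes were chosen so that
Monte-Carlo error is small relative to every asserted tolerance (e.g.
the slope-recovery standard error at n = 200, residual SD 3, baseline SD
5 is ≈ 0.04 against a ±0.1 band).

## Limitations

Two frontal channels cannot localise sources; the virtual channel
cancels only common-mode artifacts (blinks), not lateralised ones; the
plug-in MI estimator is biased upward at small n (the tests therefore
compare against permutation nulls rather than absolute thresholds); and
the trial generator's dropout is independent of outcome, so
LOCF-vs-complete-case differences here understate what informative
dropout would do in a real cohort.
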