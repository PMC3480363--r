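# basm

Brain–computer-interface attention scoring and neurofeedback trial
simulation for a two-channel frontal EEG (Fp1/Fp2) attention-training
system, with the biostatistics used to evaluate such a program in a
clinical cohort.

## What it does

Attention-training games steer an avatar with an EEG-derived attention
score: the more attentive the child, the faster the avatar moves. This
package implements the full signal chain behind such a system and the
statistics of the trial around it:

1. **Artifact screening.** Raw EEG is screened for saturated digital
   samples (|x| at the ADC rail) and disconnected electrodes (flatlined
   windows); everything within ±2 s of an abnormality is excluded.
2. **Filter-bank band-power features.** The clean signal is tiled into
   2-second blocks; each block's one-sided power spectrum is computed with
   a 256-point FFT, and power is summed over 8 contiguous bands covering
   4–30 Hz. Features are computed for Fp1, Fp2 and a *virtual channel*
   Fp1 − Fp2 — a fixed bipolar filter that cancels common-mode ocular
   artifacts — giving a 24-dimensional feature vector
   (log₁₀-transformed, averaged over blocks).
3. **Calibration.** From labeled attentive/relaxed epochs, the k = 6 most
   discriminative features are selected by mutual information
   I(feature; state) and combined by ridge regression on the ±1 state
   coding into a raw attention score (the *BASM*, higher = more
   attentive). A logistic transform anchored at the calibration class
   means maps the raw score to the 0–100 display score:
   `display = 100 · σ((raw − c)/s)`.
4. **Closed-loop sessions.** `run_session()` streams a recording through
   the scorer, smooths the display score with a trailing moving average,
   and integrates avatar distance at `speed = v_max · score/100`;
   `build_schedule()` lays out the 24-session intensive + 3-booster
   program.
5. **Trial statistics.** ADHD rating-scale scoring (9 + 9 items, 0–3 →
   IA/HI 0–27, COM 0–54), last-observation-carried-forward imputation,
   paired mean changes with t-tests, baseline-predicts-change OLS,
   Spearman correlations between the BASM change and rating-scale
   changes, and completion accounting.

Because no individual-level recordings are distributable, the package
ships generators (`simulate_eeg()`, `simulate_calibration()`,
`simulate_trial()`) that produce synthetic data with the statistical
structure the pipeline assumes — state-dependent theta/beta spectra over
pink noise, common-mode blinks, injectable saturation/disconnection
defects, and trial tables with baseline-severity-dependent improvement,
dropout and a negative ΔBASM–Δscore coupling — so every stage is testable
end to end.

## Worked example

```r
library(basm)

# calibrate a subject-specific model from labeled synthetic epochs
cal   <- simulate_calibration(n_epochs_per_label = 20, seed = 7)
model <- fit_attention_model(cal)
model
#> <attention_model> subject sim
#>   6 of 24 features selected by mutual information:
#>     Fp1_4-7.25, Fp1_7.25-10.5, Fp1_13.75-17, Fp1_17-20.25, Fp1_20.25-23.5, Fp1_23.5-26.75
#>   display map: center 0.000, scale 0.890
loo_accuracy(cal)
#> [1] 1

# a 5-minute closed-loop session on attentive-state input
trace <- run_session(model,
                     function(d) simulate_eeg(attentive_profile(), d, seed = 8),
                     duration = 300)
trace
#> <session_trace> 150 blocks (300 s), level 1
#>   mean display score 74.1, final distance 444.2 units

# outcome analysis of a simulated 20-child cohort
tb <- simulate_trial(trial_sim_config(seed = 9))
mean_change(locf(tb$ratings), "IA", 0, 8)
#> IA change, week 0 -> 8 (n = 19): mean -10.7 (SD 5.9), median -11.1 (range -26.9, -1.8)
#>   paired t = -7.86, p = 3.173e-07
basm_change_correlation(tb$ratings, tb$basm, "COM")$rho
#> [1] -0.3089...
```

The selected features sit in the theta and beta bands — exactly the bands
whose balance differs between the attentive and inattentive generator
profiles — and held-out classification is essentially perfect at this
separation. The session trace shows the avatar covering
`v_max · score/100 · duration ≈ 2 · 0.74 · 300 ≈ 444` units. In the
simulated cohort, more severe children improve more (the generator's
baseline-dependent effect) and the attention-score change correlates
negatively with the symptom change.

A command-line wrapper with the same functionality is installed at
`inst/scripts/basm` (subcommands `simulate-eeg`, `calibrate`, `score`,
`run-session`, `simulate-trial`, `analyze-trial`).

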