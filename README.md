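# synergait

Muscle synergy extraction and center-of-activity analysis for treadmill
gait EMG.

## What problem this solves

Walking at different speeds requires the nervous system to re-time the
activity of dozens of muscles. A standard way to study this is to record
multi-channel surface EMG over many gait cycles, reduce the envelopes to a
small set of **muscle synergies** — fixed non-negative muscle weightings
`W` recruited by time-varying activation coefficients `C` — and then ask
how the *timing* of each synergy's activation moves as walking speed
changes. `synergait` implements that full workflow for researchers in
motor control, gait biomechanics and rehabilitation:

- **Preprocessing**: heel-contact segmentation (discard the first 10
  cycles, analyze 30), zero-phase 40 Hz high-pass → full-wave
  rectification → 10 Hz low-pass envelopes, 100-point time normalization
  per cycle, and per-muscle peak + unit-variance normalization.
- **Extraction**: non-negative matrix factorization `M ≈ W C` (entrywise
  ≥ 0, unit-norm columns of `W`) by Lee–Seung multiplicative updates with
  20 random restarts, compiled in C++ for speed.
- **Model-order selection**: 60/40 cross-validation by whole gait cycles
  (18 train / 12 test, 10 repetitions); activations are refit on the test
  cycles with the training weightings fixed, and the number of synergies
  is the smallest rank whose 95% CI lower bound exceeds 90% global VAF
  and 75% VAF for every muscle, where
  `VAF = 100 × (1 − ‖M − WC‖²_F / ‖M‖²_F)`.
- **Shuffle control**: per-muscle independent time shuffling destroys
  inter-muscle structure while preserving each muscle's values; original
  VAF should beat the surrogate below the true rank.
- **Grouping**: synergies are matched across subjects/speeds by cosine
  similarity to a reference subject (cutoff 0.71, the two-tailed α = 0.01
  critical correlation for 12-element vectors), with duplicate resolution
  and one reference-averaging refinement pass.
- **Center of activity (CoA)**: each 100-bin activation profile is mapped
  onto the gait-cycle circle (`θ_t = 3.6°·t`), and
  `CoA = atan2(ΣsinθAct, ΣcosθAct)` gives the circular first moment of
  activation timing. CoAs are compared across speeds with one-way ANOVA +
  Tukey–Kramer post hoc tests (after wrap-safe unwrapping) and two-sample
  t-tests.
- **Kinematics**: 5 Hz zero-phase smoothing of joint angles, central
  differentiation to angular velocity/acceleration, normalized-cycle
  averaging, windowed peak accelerations (P1–P11 over stance, pre-swing
  and late-swing windows) and quadratic peak-vs-speed trends.
- **Synthetic gait generator**: a fully seeded simulator of 12-channel
  raw-like EMG (band-limited carrier amplitude-modulated by a planted
  `W C(speed)` envelope), heel contacts, speed-dependent CoA drift, and
  harmonic joint-angle trajectories with closed-form derivatives — so
  every stage has a known-answer test without any real recordings.

## Worked example

Simulate one subject walking at 4 km/h with four planted synergies, run
the full analysis, and read off the selected model order and each
synergy's center of activity:

```r
library(synergait)

gt  <- default_ground_truth(4)                       # planted synergies
cfg <- trial_config(speed = 4, n_cycles = 45, seed = 42)
rec <- synthesize_emg(gt, cfg)
rec
#> EMG recording: 12 channels, 51.4 s at 1000 Hz, 46 heel contacts, 4 km/h

cm <- preprocess_recording(rec)                      # 12 x 3000 matrix
sel <- select_rank(cm, crossval_scheme(seed = 42), max_rank = 6)
sel$report
#> Cross-validated VAF report
#>   N =  1: held-out global VAF 45.33% (95% CI lower 45.29%)
#>   N =  2: held-out global VAF 72.16% (95% CI lower 72.06%)
#>   N =  3: held-out global VAF 91.20% (95% CI lower 91.14%)
#>   N =  4: held-out global VAF 99.19% (95% CI lower 99.17%)
sel$selected_n
#> [1] 4

dec <- fit_nmf(cm, sel$selected_n, seed = 42)
coa <- sapply(seq_len(dec$N), function(i)
  center_of_activity(rowMeans(matrix(dec$C[i, ], 100)))$coa_pct)
round(coa, 1)
#> [1] 11.1 46.0 62.7 76.2
```

Rank 3 is rejected even at 91% global VAF because some muscles' VAF lower
bounds stay below 75%; rank 4 is the smallest passing model. The
recovered CoAs (11.1, 46.0, 62.7, 76.2 % of the gait cycle) sit within
about one percent bin of the planted activation centers (10, 45, 62, 75),
i.e. the support, propulsion, swing-initiation and swing synergies.

`run_pipeline(pipeline_config(...))` chains all stages over multiple
synthetic subjects and speeds and writes CSV/JSON tables (selected ranks,
CoA per subject × speed × synergy, ANOVA/Tukey results, CoA-vs-speed
slopes, kinematic peak trends, and a polar CoA figure).

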