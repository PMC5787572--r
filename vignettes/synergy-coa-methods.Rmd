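---
title: "Muscle synergies and the center of activity: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergies and the center of activity: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synergait)
```

## The model

Surface EMG envelopes from `m = 12` muscles over 30 time-normalized gait
cycles form a non-negative matrix `M` (12 × 3000: 100 bins per cycle).
The synergy model is

```
M = W C + ε,   W ≥ 0 (12 × N, unit-norm columns),   C ≥ 0 (N × 3000)
```

Each column of `W` is a muscle synergy — a fixed pattern of relative
muscle contributions — and the matching row of `C` is its activation over
the normalized cycle. The factorization is fitted by Lee–Seung
multiplicative updates minimizing the squared Frobenius error, which
keeps both factors non-negative by construction and descends
monotonically. Because the objective is non-convex, `fit_nmf()` runs 20
independent uniform-random initializations (scaled to the matrix mean)
and keeps the lowest-error restart; ties go to the lowest restart index
so results are reproducible from the seed alone.

Goodness of fit is the uncentred variance accounted for,

```
VAF = 100 × (1 − ‖M − WC‖²_F / ‖M‖²_F)
```

computed globally or per muscle row. (A published variant of this
formula omits the "1 −"; that form returns 0 for a perfect
reconstruction, so we follow the definition used by the methods
literature this analysis builds on.)

## Choosing the number of synergies

`select_rank()` / `select_num_synergies()` implement cross-validation by
whole gait cycles: 18 of the 30 analyzed cycles train the factorization,
the remaining 12 are reconstructed with the training weightings held
fixed while only activations are refit (`fit_activations_fixed_w()`,
a convex subproblem). Ten random splits give ten held-out global and
per-muscle VAF values per candidate rank; the selected rank is the
smallest whose t-based 95% CI lower bound exceeds 90% global VAF *and*
75% VAF for every muscle (strict inequalities). Partitions are uniform
without replacement — stratification in time is not enforced, as nothing
in the cycle structure warrants it. Across subjects, the consensus count
is the half-up-rounded median.

Two numerical details matter. First, cross-validating by whole cycles
(not columns) keeps train and test temporally coherent; splitting columns
would leak nearly identical neighboring bins into both sets. Second, the
CI is computed over the 10 repetition means with the t quantile (n = 10);
with noise-free data the spread collapses and the bound equals the mean.

The per-muscle shuffle control (`compare_shuffled_vaf()`) guards against
the factorization "explaining" data with no inter-muscle structure: each
muscle's samples are permuted independently over the full concatenated
record (the strongest removal of inter-muscle correlation; per-cycle
block shuffling would be a weaker alternative), and the original VAF
should exceed the surrogate's at every rank up to the true one.

## Center of activity and circular statistics

Activation timing is summarized by the circular first moment of each
100-bin activation profile: bin `t` maps to `θ_t = 3.6°·t` (so bin 100 is
360° ≡ 0°), and

```
A = Σ cos(θ_t)·Act_t,   B = Σ sin(θ_t)·Act_t,   CoA = atan2(B, A)
```

mapped to [0, 360), or divided by 3.6 for % gait cycle. The two-argument
arctangent is essential; `atan(B/A)` alone misplaces centers in three of
four quadrants. A CoA is refused (error, never a silent 0°) when the
activation is all zero or its resultant length `√(A²+B²)/ΣAct` is
numerically zero — a perfectly balanced profile has no center.

Across-speed comparisons use ordinary one-way ANOVA with Tukey–Kramer
post hoc tests and two-sample t-tests, applied to CoAs *unwrapped* about
their grand circular mean (every value moved within ±180° of it). This
preserves the familiar linear tests while fixing the wraparound artifact
whereby clusters at 98% and 2% of the cycle would otherwise appear ~96%
apart; a flag disables unwrapping for strict linear treatment. Unwrapping
is exact as long as the per-synergy CoA spread stays well inside half a
cycle, which holds for unimodal gait activations.

## The synthetic gait generator

`synthesize_emg()` inverts the analysis model so every stage has a
known answer. Activation profiles are circular Gaussians
(von-Mises-shaped bumps, `exp(κ(cos(φ−φ₀)−1))`): unimodal like real
bursts, periodic so a bump at 98% wraps continuously, and exactly equal
to their amplitude at the center. Speed dependence enters as a linear
drift of each center, `center(speed) = wrap(center(ref) + slope·Δspeed)`;
the default five-synergy ground truth drifts the support and
swing-initiation synergies earlier (−1.2 and −1.0 %/km/h), the swing and
late-swing synergies later (+1.0, +1.2), and leaves propulsion flat —
the qualitative pattern the analysis is meant to detect. Cycle durations
are truncated-normal (floor 0.3 s; default CV 3%, mean shortening
linearly with speed as real stride times do). The raw signal is a 20–450
Hz band-limited white-noise carrier amplitude-modulated by the envelope
`W C(speed)` resampled to each cycle's duration, plus additive broadband
noise scaled to a fraction of the channel's envelope peak (default 5%;
the data report no per-cycle envelope variability statistics, so this is
a free, exposed choice). Multi-subject simulations perturb the shared
weightings (sd 0.05) and jitter activation centers by 1% of the cycle —
without subject-level timing variability, between-subject CIs on CoA
would be unrealistically degenerate.

What the generator does *not* emulate: motor-unit physiology (the
carrier is filtered noise, which is all that matters after
rectification/smoothing), inter-muscle crosstalk, electrode artifacts,
nonstationarity within a trial, and 3D marker kinematics (joint angles
are synthesized directly as ≤ 4 harmonics per joint with speed-scaled
amplitudes and closed-form derivatives). Passing tests therefore
demonstrate the *pipeline's* correctness under the model's assumptions,
not robustness to every artifact of real recordings.

One consequence of rectifying a stochastic carrier deserves note: even
with zero additive noise the estimated envelope carries irreducible
estimation noise (the 10 Hz smoother averages finitely many carrier
samples), so recovery checks on the raw-signal path use correlation and
cosine criteria, while exact-rank claims (VAF ≥ 99% at the true rank)
are made on the directly constructed envelope matrix.

## Preprocessing and kinematics choices

Filters are 4th-order Butterworth applied forward–backward: cutoffs are
the conventional 40 Hz (high-pass), 10 Hz (envelope low-pass) and 5 Hz
(marker low-pass); zero-phase realization is non-negotiable here because
any group delay would bias the CoA. Signals are odd-reflection padded
before filtering so startup transients decay in the padding rather than
the data. Time normalization is linear interpolation to 100 points per
cycle — it cannot overshoot into negative values the way higher-order
interpolants can. Normalization for extraction divides each muscle by
its peak over the analyzed condition and then by its SD (unit variance),
so no single high-amplitude muscle dominates the factorization; the
peak is taken within-condition since extraction is per-speed, and the
factors are stored so `denormalize_weightings()` can map fitted
weightings back to raw envelope units (necessary before comparing
weightings across normalizations or to ground truth).

Differentiation is by central differences in the time domain *before*
cycle normalization, preserving deg/s and deg/s²; on band-limited gait
signals differentiation and time normalization commute to within the
interpolation error. The eleven peak angular accelerations are windowed
extrema of the cycle-averaged acceleration — both directions of all
three joints in stance (0–30%), two pre-swing peaks (45–65%) and three
late-swing peaks (85–100%). The phases are anatomically meaningful but
their numeric spans are configuration defaults (`default_peak_windows()`),
chosen to bracket the reported mean peak timings; an extremum on a window
edge is flagged as a boundary peak rather than trusted. Peak-vs-speed
trends are ordinary quadratic least squares.

## Problem sizes and determinism

The test suite and the acceptance script run at the study's own scale —
12 muscles, 30 analyzed cycles (100 bins each), 20 NMF restarts, 10
cross-validation repetitions — with 20-seed replications for the
stochastic claims and 2–8 km/h speed sweeps over 4 synthetic subjects
for the CoA-drift recovery; smaller planted matrices are used where a
property does not depend on scale. Every generator and fit is a pure
function of its parameters and one integer seed; the pipeline derives
per-stage seeds from a single root seed, so identical configurations
reproduce byte-identical tables.

## Known limitations

- Selection can be conservative on data whose true synergies overlap
  heavily in time; the 75% per-muscle bound is then the binding
  constraint, as the example in the README shows.
- The 0.71 grouping cutoff is the α = 0.01 critical correlation for
  12-element vectors (`critical_similarity()`); with other channel
  counts the threshold should be recomputed, not reused.
- Tukey–Kramer on unwrapped angles is a linear approximation to a
  genuinely circular comparison; it is accurate for concentrated CoA
  distributions but not for dispersions approaching the half-cycle.
- The generator's speed scalings (amplitudes, stride time) are smooth
  and monotone by construction; it cannot exhibit the discontinuities
  of a real walk-to-run transition.
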