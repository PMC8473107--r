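---
title: "Models and design choices in roboaffect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in roboaffect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(roboaffect)
```

This vignette is the package's own account of the science it implements:
the signal model, the estimation and policy procedures, the numerical
choices, and — because several steps of the original method are only
verbally specified — the design decisions the package had to make and why.

## 1. Signal model and feature extraction

The pipeline assumes two sensor streams that are already *feature-level*:
R-R intervals (ms) from a pulse sensor, and the proprietary Attention and
Meditation indices (0–100) from a consumer EEG headset. Raw-waveform
processing (R-peak detection, band power) is deliberately out of scope:
the method starts where the sensors' own firmware stops, and the EEG
indices' internal algorithm is unpublished, so nothing below this level
can be reproduced anyway.

**pNN50 (valence proxy).** `compute_pnn50()` counts successive absolute
R-R differences strictly greater than 50 ms. The conventional statistic
is defined over "30 adjacent intervals", which is ambiguous: 30 intervals
give 29 differences. The package resolves this as **31 intervals → 30
differences, denominator 30**, so the count matches the number of
adjacent pairs named; `n_diff` is configurable for users who prefer the
29-difference reading. pNN50 depends only on successive differences, so
it is invariant under a constant shift of all intervals — a property the
test suite checks.

**Arousal.** `arousal_index()` is simply Attention − Meditation, in
[−100, 100]. Higher beta-weighted Attention relative to alpha-weighted
Meditation is read as higher activation.

**1 Hz alignment.** The two sensors are unsynchronized, so
`align_streams()` samples both at each integer second by carrying the
most recent value forward. No interpolation is used — carry-forward is
what a real-time system actually has available at second *t* — and
seconds before the first sample of either stream are dropped rather than
back-filled. Windows are half-open `[start, stop)` throughout, on a
0-based session clock. A 75 s stimulus therefore yields 75 aligned
seconds once both streams are live.

## 2. Emotion estimation on the circumplex

Raw features are mapped to normalized coordinates by
`normalize_affect()`:

- `arousal = clamp((raw − baseline_arousal) / 100, −1, 1)` — dividing by
  100 puts the EEG axis on the same scale as valence so that Euclidean
  distance is meaningful;
- `valence = clamp(pNN50 − baseline_pnn50, −1, 1)`.

The valence mapping was a genuinely open design point: pNN50 is
non-negative, but the circumplex valence axis is signed. The package
centers on the participant's own 60 s resting baseline (so "more vagal
activity than at rest" is positive valence), which matches how the
original protocol interprets values *relative to baseline*. A fixed-0.5
midpoint alternative (`valence_normalization = "midpoint"`) is provided
for pipelines without a rest segment. Baselines require at least 30
aligned seconds; the protocol's 60 s rest comfortably exceeds this even
after the ~25 s the sliding pNN50 window needs to warm up.

`classify_quadrant()` assigns the four labels by coordinate sign, with
the documented tie rule that axis points go to the *non-negative* side
(the origin is `happy`). `intensity_level()` quantizes the Euclidean norm
into five equal-width bins over `[0, √2]` — the source method specifies
five levels driven by the length to the point `(x, y)` but no bin edges,
so equal bins on the normalized plane are the least-informative choice;
level 5 begins at `4√2/5` and level 1 contains the origin.

`cumulative_estimate()` re-evaluates the *expanding* mean of all samples
since stimulus onset at every 2.5 s tick ("cumulative", not a sliding
window), then classifies and grades that mean. Ticks before the first
sample defer the estimate rather than erroring. The 2.5 s default is the
update interval found to give the best impression of the robot in the
antecedent work this method builds on.

## 3. Expression policies

`select_expression()` implements the three fixed conditions
(synchronized / inversely synchronized / funny); `invert_emotion()` is
the diagonal involution happy↔sad, angry↔relaxed. In **every** condition
the intensity level is copied live from the estimate — including funny,
whose label alone is fixed.

The personalization rule has three stated ingredients: the condition with
the highest session-average pNN50, the Like-click times, and the
expression on display at those times. Two details are unstated and were
fixed as follows:

- *tie on average pNN50*: fixed priority synchronized >
  inversely_synchronized > funny (the conditions' natural ordering, and
  deterministic);
- *combining several liked expressions into one displayed expression*:
  the modal liked label, ties broken by the most recent like, with the
  intensity always taken from the live estimate. "At that timing" is
  interpreted as the command active in the 2.5 s display frame containing
  the click.

With no likes recorded the policy delegates to the chosen condition.

## 4. Preference model

`build_dataset()` labels each aligned second with the polarity of the
earliest click whose 30 s lookback window contains it. The source
protocol describes both "~75 labeled entries per clip" and "data captured
for 30 s before the first mouse click"; these conflict, and the package
generalizes the lookback to *every* click (earlier click wins on
overlap), with `first_click_only = TRUE` reproducing the literal
single-window reading.

`fit_logistic()` fits `logit(p) = β₀ + β₁·arousal + β₂·valence` by
IRLS/Newton with a ridge penalty of `1e−6` (so complete separation — easy
to produce with few clicks — still has a finite optimum), gradient
max-norm tolerance `1e−8`, and a 100-iteration cap. `stats::glm` serves
as an independent cross-check in the tests; on non-separable data the two
agree to `1e−5`. Classification uses threshold 0.5.

`assign_group()` condenses a participant into one of five groups from the
centroid of their like-labeled samples. The groups are only verbally
described in the source (high arousal regardless of pNN50; relaxed;
pleasant and relaxed; unpleasant and concentrating; others/middle), so
the package uses an explicit ordered rule table with threshold
`θ = 0.25` (configurable) on the normalized plane.
`click_association_test()` is Pearson's chi-square of independence on the
k×2 condition-by-polarity table, without continuity correction.

## 5. What the synthetic generator emulates — and what it does not

`generate_session()` reproduces the session protocol: 60 s rest (for the
baseline), then a 75 s stimulus window with 2.5 s expression ticks and
free clicking. Its parts:

- **RRI** (`generate_rri()`): a bounded random walk around the mean
  interval (800 ms default, deviation capped at ±150 ms) whose
  successive-difference magnitudes come from an exceedance mixture —
  U(55, 120) ms with the target pNN50 rate, U(0, 45) ms otherwise — with
  the number of exceedances allocated as an (almost) exact count. The
  target pNN50 is therefore controlled directly and realized values track
  it tightly; q = 0 and q = 1 are hit exactly.
- **EEG** (`generate_eeg()`): Attention/Meditation placed symmetrically
  around 50 at ±target/2 with independent N(0, 5) noise, clamped to
  [0, 100], so the expected difference equals the target arousal.
- **Clicks** (`generate_clicks()`): a Poisson process (default 24
  clicks/min ≈ one judgement per 2.5 s display frame) whose polarities
  are Bernoulli draws from the ground-truth logistic law evaluated at the
  aligned features — the generative model *is* the model the fitter
  assumes, which is exactly what a parameter-recovery test requires.
- One RNG stream per session, seeded from the participant spec and
  consumed in the fixed order RRI → EEG → clicks, makes sessions
  byte-identical under a fixed seed.

The generator does **not** emulate music-evoked emotion dynamics,
reaction times, artifacts/ectopic beats, or any feedback of the displayed
expression on the signals *within* a session. Consequently, passing tests
show that the pipeline's computations are correct and that its inferences
recover the structure its own model assumes — they do not show that real
participants behave this way.

**The personalization follow-up** needs the expression condition to
influence physiology, as it did for real participants. This enters
through per-condition stimulus signal specs (defaults: pNN50 targets 0.40
/ 0.22 / 0.30 for synchronized / inverse / funny, small arousal offsets).
The personalized replay uses the chosen condition's spec **plus a
`personalized_boost` of +0.10 on the target pNN50**, modeling that the
personalized robot shows the liked expression in *every* frame whereas
the originating condition showed it only intermittently, so the valence
response is at least as strong. This is the one place the simulation
encodes a directional assumption rather than a neutral mechanism; it is a
parameter, visible in `run_followup()`, and setting it to 0 makes the
personalized session statistically identical to the chosen condition.

## 6. Problem sizes and numerical notes

The test suite and the acceptance script run at desk scale: 2000-sample
logistic recoveries over 10 seeds, 75 s sessions (~94 beats, 75 aligned
seconds, 30 expression ticks), 10 simulated four-session studies for the
personalization check, and a 41×41 grid for the quadrant classifier.
Running means are compared to brute-force recomputation at tolerance
1e−9; the chi-square statistic to an explicit Σ(O−E)²/E loop at 1e−10.
Degenerate inputs are first-class: windows shorter than 31 intervals,
empty streams, single-class click labels, all-zero contingency margins
and like-free participants all raise typed conditions
(`roboaffect_*` classes) naming the offending field.

## 7. Known limitations

- pNN50 is treated as a valence proxy as the method prescribes; HRV is at
  best an indirect and individually variable valence correlate.
- No artifact rejection: implausible R-R intervals (outside 300–2000 ms)
  are flagged with a warning but retained, since the method states no
  rejection rule.
- Resubstitution (training-set) accuracy is reported, matching the
  original evaluation; it is optimistic relative to held-out accuracy.
- The five-group assignment depends on the invented θ = 0.25 threshold;
  different thresholds will re-partition borderline participants.
- The follow-up's directional conclusion inherits the
  `personalized_boost` assumption discussed above.
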