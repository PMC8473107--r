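# roboaffect

Affect-aware robots need to decide, every couple of seconds, which facial
expression to show — and different people like different answers.
`roboaffect` implements a complete desk-scale pipeline for that problem:
it estimates a user's emotional state from two wearable biosignals, drives
a robot's symbolic facial expression from the estimate under several
policies, and learns each user's expression preferences from their own
like/dislike clicks so that the policy can be personalized.

The package is aimed at human–robot-interaction and affective-computing
researchers who want to prototype and test expression-selection policies
without sensor hardware: a synthetic session generator with controllable
signal statistics and a ground-truth preference model stands in for the
EEG headset, pulse sensor, and participant.

## The method

**Emotion estimation.** Two physiological proxies are placed on Russell's
circumplex model of affect:

- *valence* (horizontal axis) — pNN50, the proportion of successive R-R
  interval differences exceeding 50 ms, computed over a sliding window of
  31 intervals (30 adjacent differences):
  `pNN50 = #{ |RRI[i+1] − RRI[i]| > 50 ms } / 30`;
- *arousal* (vertical axis) — the difference of the EEG headset's
  Attention and Meditation indices (each 0–100): `Attention − Meditation`.

The two unsynchronized streams are merged on a 1 Hz clock by carrying the
most recent value of each forward. After a 60 s rest period fixes a
baseline, samples are normalized onto `[−1, 1]²`
(`arousal = (raw − baseline)/100`, `valence = pNN50 − baseline pNN50`,
both clamped). Every 2.5 s the running mean of all samples since stimulus
onset is classified into a quadrant (happy / angry / sad / relaxed; axis
points go to the non-negative side) and graded into one of five intensity
levels by the Euclidean distance to the origin (five equal bins over
`[0, √2]`).

**Expression policies.** Each 2.5 s estimate becomes an expression
command: `synchronized` mirrors the estimated emotion,
`inversely_synchronized` shows its diagonal opposite (happy↔sad,
angry↔relaxed), `funny` always shows the funny face; intensity follows
the live estimate in every condition. The `personalized` policy picks the
condition whose session had the highest average pNN50, collects the
expressions on display when the user clicked "Like", and replays the
modal liked expression.

**Preference model.** Each click labels the 30 s of aligned samples
before it (1 = like, 0 = dislike; the earlier click wins on overlap), and
a logistic regression

```
logit(p_like) = β₀ + β₁·arousal + β₂·valence,  p = 1 / (1 + e^(−logit))
```

is fitted by iteratively reweighted least squares (ridge `1e−6` guards
against complete separation). Models are evaluated by confusion-matrix
accuracy `ACC = (TP + TN)/(TP + FP + FN + TN)` at threshold 0.5,
summarized into five preference groups from the like-click centroid, and
click–condition association is tested with Pearson's chi-square.

## Worked example

```r
library(roboaffect)

## recover a known preference model from simulated labeled samples
d <- simulate_preference_samples(2000, beta = c(0, 2, 3), seed = 1)
m <- fit_logistic(d)
m
#> <preference_model> logit(p_like) = -0.188 +2.053*arousal +3.038*valence
#>   n = 2000, converged: TRUE
accuracy(confusion_counts(m, d))
#> [1] 0.7905

## simulate a full study: three fixed-condition sessions, then the
## personalized follow-up, for a strongly valence-driven participant
part <- participant_spec(true_beta = c(0, 0.5, 8), click_rate = 24, seed = 3)
study <- simulate_followup_study(part)
study$followup
#> <followup_report> chosen condition: synchronized
#>   like ratios: synchronized 0.74, inversely_synchronized 0.48, funny 0.54, personalized 0.91
#>   association: X2(3) = 16.97, p = 0.000717
```

The fitted coefficients land within sampling error of the generating
`(0, 2, 3)`; the resubstitution accuracy (79.1%) sits just under the
generating model's Bayes accuracy (80.0%). In the simulated study the
personalized condition reaches the highest like-click ratio and the
chi-square test flags a clear click–condition association.

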