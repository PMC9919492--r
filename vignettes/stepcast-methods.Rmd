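---
title: "Forecasting near-term walking from wearable step streams: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting near-term walking from wearable step streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepcast)
```

## The problem

Just-in-time adaptive interventions (JITAIs) for physical activity need a
decision signal: *is this a moment at which a walking suggestion could
matter?* A pragmatic formulation is a binary forecast — will the person take
a walk of at least five minutes within the next three hours — built only
from their own recent walking history and the calendar. `stepcast`
implements that full protocol: bout detection, hourly state reduction,
one-hot featurization, class balancing, a shared K-fold harness, six
classifier families, and random search over multilayer-perceptron (MLP)
architectures, evaluated by accuracy, sensitivity, specificity and the
Matthews correlation coefficient (MCC).

## From step counts to hourly states

The raw input is a minute-resolution step stream per participant, as
produced by a step-triggered wrist device: a minute appears only when steps
were taken, and whole calendar days vanish when the device is not worn.
Three reduction rules are applied, in order:

* participants with fewer than `min_days = 10` distinct recorded days are
  excluded (too little history to featurize meaningfully);
* a **walk bout** is a maximal run of consecutive minutes — timestamps
  differing by exactly one minute; any gap breaks the run — each with at
  least `min_spm = 60` steps, of length at least `min_len = 5` minutes.
  Slower or shorter bursts are treated as background movement, not walks;
* each clock hour in a participant's span (first recorded day's midnight to
  last recorded day's 23:00) becomes exactly one of `ACTIVE` (contains at
  least one bout minute), `MISSING` (its calendar day has no records), or
  `INACTIVE` (everything else).

Two points here were genuinely open and are package decisions. First, "fewer
than 10 days of data" is read as *distinct recorded calendar days*, not
elapsed span. Second, a bout that crosses an hour boundary marks **both**
hours active — any-overlap is the only rule under which "the hour contains a
walk" is symmetric in time. Third, missingness is day-granular: hours on a
day with any records are never `MISSING`. Partial-day device dropout is
deliberately not modelled; the missed-day accounting in the data this
emulates is day-level.

## Featurization

Each participant-hour anchor yields a binary vector of length 2,594:

| block | width | encoding |
|---|---|---|
| hour of day | 24 | one-hot |
| day of week | 7 | one-hot, Monday first |
| month | 12 | one-hot |
| day of month | 31 | one-hot |
| lag history | 840 × 3 | each of the 840 preceding hours one-hot as ACTIVE/INACTIVE/MISSING |

so every instance has exactly 4 + 840 = 844 ones. The lag history is the
840 hours (5 weeks) immediately preceding the anchor; hours before the
participant's span are encoded `MISSING`, which is what lets anchors near
the start of a record still form instances. The outcome window is
`[anchor, anchor + 3)` — the anchor hour itself is the first predicted hour,
history ends at anchor − 1. The label is 1 if any window hour is `ACTIVE`;
0 if none is and at least one is observed; and no instance is emitted when
the window leaves the span or is wholly `MISSING` ("walked" is observable,
"did not walk" requires observation). Anchors advance hour by hour, so
outcome windows overlap — that is intentional and matches the
participant-hours accounting of the design this follows.

## Balancing and the fold harness

Sleep and sedentary time make non-walking hours several times more common
than walking hours. The package balances by **undersampling**: all minority
instances are kept and the majority class is sampled uniformly without
replacement to parity. Balancing happens once, globally, before the single
shuffle that defines the folds — so the folds are identical for every
algorithm and every architecture trial, and algorithm comparisons are
paired. Oversampling (duplicating minority instances) is deliberately not
the default: duplicated instances can land on both sides of a fold
boundary, leaking behavior patterns from train to test and inflating
accuracy; undersampling makes that mechanism impossible.

Fold `i` of K = 10 uses part `i` for testing and the cyclic successor part
for tuning, leaving 8 parts for training. The cyclic-successor choice is a
package decision (the tuning part's placement was unspecified); it keeps
every fold structurally identical. The split is instance-level, matching
the protocol's shuffle; `K ≥ 3` is enforced so the three roles stay
disjoint. The tune part steers early stopping for the MLP only; the other
families fit on the train part alone and record the tune part as unused.

## Classifiers

Six families sit behind one fit/predict contract with a 0.5 probability
threshold: logistic regression (`glmnet`, lightly ridge-penalized at
λ = 10⁻³ with a short warm-start path — plain IRLS is impractical at 2,594
predictors and the penalty at this λ is negligible), RBF-kernel SVM
(`e1071`), gradient-boosted trees (`xgboost`), decision tree (`rpart`),
random forest (`ranger`), and the MLP. Hyperparameters not fixed by the
protocol fall through to each backend's defaults and are snapshotted into
the fit report, so a run documents exactly what it did.

The MLP is implemented in-package: dense layers with ReLU activations, a
single sigmoid output, binary cross-entropy, Adam (lr 10⁻³, batch 64), and
early stopping on tune-part loss with configurable patience. This is the one
component written here rather than delegated, because no installed R backend
trains networks with more than one hidden layer; its optimizer, activation
and epoch budget are package choices (none were specified by the protocol)
and are exposed as hyperparameters.

**Architecture search.** `random_search()` samples a depth uniform on
1..`max_layers` (default 5) and widths uniform on `width_choices` (default
{4, 8, …, 256}), evaluates every candidate on the *same* folds, ranks by
mean cross-validated accuracy — accuracy is the optimization metric since
the classes are balanced; MCC is recorded but never optimized — and keeps
the top 3. Ties break by higher mean MCC, then lower trial index, for
determinism. The search-space ranges are package choices spanning under- to
over-parameterized networks at desk scale.

## Metrics

All metrics live on confusion counts (stored as reals so fold means are
representable): accuracy (TP+TN)/N, sensitivity TP/(TP+FN), specificity
TN/(TN+FP), and MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
When a marginal is zero MCC is undefined and the package returns 0 with a
warning (a common convention, made explicit here). Aggregation reports
**both** the mean of per-fold metrics (with sample SD, denominator K − 1)
and the metrics of the mean confusion matrix: the two legitimately differ in
the third decimal because a ratio of means is not a mean of ratios, and
published tables that mix them look inconsistent unless both are shown.
Fit wall-clock is measured around the fit call only and reported
descriptively (min/max/mean/SD and mean ± 1.96 SD); absolute timings are
hardware-bound and are never an acceptance quantity.

## The synthetic generator

The original minute-level stream is not publicly deposited, so the package
generates cohorts that emulate its printed structure. Per non-missing day,
walk-bout starts are Poisson per hour-of-week cell of a 24 × 7 rate matrix,
placed at uniform minutes; overlapping bouts merge; a bout reaching midnight
is truncated (night rates are ≈ 0, so this is negligible). Bout durations
are lognormal (meanlog 2.05, sdlog 0.70) floored at 5 min — giving mean
≈ 10.3, SD ≈ 7.6 min — so every generated bout is detectable by
construction. Bout minutes draw cadence 60 + Poisson(45) steps/min;
background minutes (Poisson mean 119/day over 06:00–23:00) draw a truncated
geometric on 1–59, targeting ≈ 146 recorded minutes/day in total. Each
calendar day is wholly missing with probability 0.369. Participant `i`
derives its own child seed from `(seed, i)`, so streams are stable under
cohort-size changes.

The default preset's week-average rate (2.70 expected starts/day) is set so
that *detected* bouts — after overlap merging — average ≈ 2.6/day. The
distributional families themselves are modelling choices: the emulated
summary statistics pin means and SDs, not shapes. One printed combination
is jointly infeasible — 2.6 walks/day of mean 10.3 min cannot coexist with
only 0.6 walking *hours*/day unless walks pile into the same clock hours —
so calibration prioritizes walks/day, walk length and missingness, the
three statistics the validation suite checks. The cohort summary estimates
the missing-day fraction over the first-to-last recorded-day span (the true
study length is not observable from data alone), a small negative bias that
stays well inside the validation band.

Three presets ship as YAML profiles: `default` (circadian weekday/weekend
structure), `null` (the same marginal rate spread flat over all 168
hour-of-week cells — no temporal signal, so after balancing no classifier
should beat chance on label-shuffled versions), and `structured` (walk mass
concentrated in weekday commute/lunch hours — strongly predictable from
calendar features alone). The null/structured pair is what turns "the
pipeline runs" into "the pipeline recovers signal iff signal exists".

What passing on synthetic data does **not** show: the generator has no
autocorrelated wear patterns, no weather/context effects, no
intervention-induced behavior change, and no between-participant
heterogeneity in circadian shape beyond Poisson noise. Real-data accuracies
are therefore not reproduced here — the published headline numbers are
instead verified as *metric identities* (recomputing the reported metrics
from the reported mean confusion matrices, shipped in
`inst/extdata/reference_confusion.csv`). Three of the eighteen printed
row/metric pairs disagree with their own mean matrix at the third decimal
(logistic and SVM and decision-tree specificity, e.g. 609.0/812.5 = 0.7495
prints as 0.749); these are rounding artifacts of mean-of-fold-metrics
versus metric-of-mean-matrix and are excluded from the identity checks.

## Problem sizes and numerics

The validation suite runs the full protocol at the emulated study scale —
41 participants × 43 days (≈ 28,000 instances, ≈ 12,000 after balancing)
— for the logistic signal-recovery check and generator calibration
(30 replicate cohorts), and at reduced scale (6 participants × 14 days,
K = 5, 15 search trials, capped epochs) for the all-family chance-level and
search-behavior properties, sizes chosen so the whole suite stays a
desk-scale run. Degenerate inputs are defined, not accidental: empty series
give empty bout lists; all-missing participants yield no instances;
single-class sets refuse to balance; `K > n` and `K < 3` are errors;
single-class test folds are flagged and metrics computed where defined.
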