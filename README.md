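# stepcast

Will this person take a walk in the next three hours? `stepcast` is an R
implementation of a complete development-and-validation protocol for
answering that question from consumer-wearable step counts, aimed at
researchers building just-in-time adaptive interventions (JITAIs) for
physical activity: a mobile intervention should nudge someone when a walk is
*possible but not certain*, which requires exactly this kind of short-horizon
behavioral forecast.

The pipeline:

1. **Walk-bout detection.** Minute-level step counts are reduced to *walk
   bouts*: maximal runs of ≥ 5 consecutive minutes at ≥ 60 steps/min.
   Participants with fewer than 10 recorded days are excluded.
2. **Hourly states.** Every clock hour becomes `ACTIVE` (contains a bout
   minute), `INACTIVE`, or `MISSING` (a wholly unrecorded calendar day).
3. **Featurization.** Each participant-hour anchor yields a 2,594-column
   binary vector: one-hot hour-of-day (24), day-of-week (7), month (12),
   day-of-month (31), plus the 840 preceding hours each one-hot encoded as
   ACTIVE/INACTIVE/MISSING (5 weeks × 168 h × 3). The label is 1 iff any of
   the next 3 hours is ACTIVE.
4. **Balancing and folds.** Non-walking hours vastly outnumber walking
   hours; the majority class is undersampled to parity, then a single
   shuffle defines K = 10 folds with an 8-train / 1-tune / 1-test rotation
   shared by every algorithm.
5. **Six classifier families** behind one fit/predict contract: logistic
   regression (glmnet), RBF-kernel SVM (e1071), gradient-boosted trees
   (xgboost), decision tree (rpart), random forest (ranger), and an
   in-package multilayer perceptron whose hidden-layer architecture is
   chosen by random search (depth and widths sampled uniformly, candidates
   ranked by cross-validated accuracy, top 3 retained).
6. **Evaluation** by accuracy, sensitivity, specificity and the Matthews
   correlation coefficient,
   MCC = (TP·TN − FP·FN)/√((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
   reported as mean (SD) over folds together with mean confusion matrices
   and descriptive fit timings.

Because the original HeartSteps minute-level stream is not publicly
deposited, the package ships a **synthetic step-stream generator** that
reproduces its printed structure (≈ 2.6 walk bouts/day of mean length
≈ 10.3 min, ≈ 36.9 % missing days, ≈ 146 recorded min/day) with circadian
and weekly rate profiles, plus `null` (no temporal signal) and `structured`
(strong clock signal) presets used by the property tests.

## Worked example

```r
library(stepcast)

cfg   <- generator_preset("structured", seed = 7)      # 41 participants x 43 days
pre   <- preprocess_cohort(simulate_cohort(cfg))
inst  <- build_instances(pre$states)
inst
#> <instance_set> 28352 instances x 2594 features; 5941 active / 22411 inactive

bal   <- undersample_balance(inst, seed = child_seed(7, 2))
folds <- shuffle_and_fold(bal, K = 10, seed = child_seed(7, 3))
res   <- run_kfold(bal, folds, classifier_spec("logistic_regression", seed = 3))
res$summary
#>        metric      mean         sd
#> 1    accuracy 0.8391691 0.01070632
#> 2         mcc 0.6804642 0.02089279
#> 3 sensitivity 0.8758285 0.01562662
#> 4 specificity 0.8030434 0.01729205
```

28,352 participant-hours survive the skip rules; 5,941 (21 %) are followed
by a walk within 3 h. After undersampling to 5,941 + 5,941 instances,
logistic regression reaches 83.9 % (SD 1.1 %) 10-fold accuracy on this
strongly clock-driven preset — walking here is concentrated in weekday
commute/lunch hours, so calendar indicators alone carry most of the signal
(a majority-vote baseline sits at ≈ 49 %). An MLP architecture search is one
call away:

```r
sr <- random_search(bal, folds, search_space(n_trials = 15, seed = 17),
                    hyperparams = list(epochs = 20, patience = 3))
sr$trials[sr$top, c("architecture", "accuracy_mean")]
```

The whole protocol also runs from a shell via the installed script
(`inst/scripts/stepcast`): `stepcast all --out runs/demo --preset structured
--seed 7`.

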