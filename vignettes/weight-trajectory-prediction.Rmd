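---
title: "Predicting long-term weight change from self-reported weight logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting long-term weight change from self-reported weight logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Web-based weight-coaching programs collect self-reported weight logs:
irregular, noisy sequences of (day, weight) pairs for each participant.
Early in an intervention it is valuable to know whether a participant is on
track, because reinforcement works best when it arrives before the outcome
is settled. `wtraj` implements a trajectory-based prediction framework for
this setting: the nine-month weight-change *outcome* is defined by
clustering whole trajectories, and per-time-frame classifiers map the data
available after 0.5--8 months to that outcome.

All weight information is handled as percent change relative to the
baseline (first) entry, $100\,(w(d) - w(0))/w(0)$, on an integer daily
grid; days between entries are linearly interpolated. Percent change makes
trajectories comparable across body sizes, and the daily grid makes
dynamic time warping (DTW) and per-day averaging well defined.

## Outcome classes from trajectory clustering

The outcome is not a fixed threshold but five empirically derived classes
(high/moderate/insufficient weight loss, low/high weight gain). They are
obtained in two stages:

1. **Consensus agglomerative clustering.** A DTW distance matrix over the
   day 0--270 series feeds several hierarchical clusterings. We use three
   linkage criteria (average, complete, Ward) on the same DTW matrix as the
   independent clustering variants; the variants' labels are matched by
   maximal overlap (exact assignment over the $k! = 120$ permutations,
   which coincides with Hungarian matching at this size), and only
   individuals on which *all* variants agree contribute to the initial
   per-day mean trajectories. This protects the initial centroids from
   individuals whose cluster membership is ambiguous.
2. **DTW $k$-means.** Lloyd iterations over the whole cohort: assignment by
   smallest DTW distance to the current means (ties to the lower cluster
   index), update by the arithmetic per-day mean of the assigned series.
   Means are per-day averages rather than DTW barycenters because all
   series share the daily grid and the per-day mean is what the refinement
   stage is asked to refine. Iteration stops when assignments are
   unchanged; an empty cluster keeps its previous mean and raises a
   warning.

DTW is used because the classes should reflect the *shape* of a
trajectory: someone who loses quickly and plateaus should sit close to
someone who reaches the same plateau more slowly. The DTW local cost is
the squared difference with a final square root (the common convention of
DTW libraries, giving distances on the data scale); an absolute-difference
cost and a Sakoe--Chiba band are available in `dtw_config()` for
sensitivity analysis but are not used by default, and no band is applied
by default.

The five final clusters are ordered by their day-270 mean value and named
`high_loss`, `moderate_loss`, `insufficient_loss`, `low_gain`,
`high_gain`. The three-class scheme merges the two loss classes and the
two gain classes. For a cohort that is not available for retraining, the
package ships the originally reported regression-to-class cutoffs
(`default_cutoffs()`: -9.2, -2.4, -0.1, 2.2 percent for five classes;
-2.4, -0.1 for three); any retraining regenerates cohort-specific values.

## Prediction models

For each of nine time frames (0.5, 1, 2, ..., 8 months; one month is 30
days), each class scheme, and each of six supervised methods, one model is
trained to predict the day-270 class from the data in the frame. The input
encodings are:

* `bmi_last`: baseline BMI and the percent change at the frame's last day;
* `bmi_history`: baseline BMI and the percent change at the end of every
  grid frame up to the current one;
* `dtw_dists`: the DTW distances from the observed (frame-limited) series
  to the five cluster means truncated to the frame -- truncation matters,
  because comparing a 15-day series against a 270-day mean would be
  dominated by the length difference;
* `daily`: baseline BMI plus all daily values (perceptron only).

The shipped per-method defaults are the encodings that performed best for
the original framework (`default_encodings()`); setting
`wtraj_control(select_encoding = TRUE)` re-runs the selection sweep and
keeps, per method, the encoding with the best mean cross-validated
accuracy.

The six methods are multinomial logistic regression (`nnet::multinom`,
L2 decay 0.01), linear regression (`stats::lm`), Gaussian naive Bayes
(`e1071::naiveBayes`), RBF-kernel support vector classification and
regression (`e1071::svm`, cost 1, internally standardized), and a
single-hidden-layer perceptron (`nnet::nnet`, hidden size twice the input
length, decay 0.01, at most 300 optimizer iterations, seeded
initialization). The original report does not record hyperparameters, so
these are deliberately library-default-grade choices, all overridable
through `wtraj_control()`. Features are standardized for the logistic
model and the perceptron with means and scales estimated on the training
folds only, to avoid cross-validation leakage; the SVMs use their own
internal training-set scaling.

Model quality is assessed with fivefold class-stratified cross-validation:
within each outcome class, members are dealt evenly across folds
(remainders round-robin from the first fold), so every fold sees every
class. Every individual is assigned to exactly one fold; we do not discard
surplus members of larger classes, which is the less wasteful reading of
equal-per-class sampling.

### Regression-to-class conversion

The regression-type methods predict the day-270 percent change and need
cutoffs to become classifiers. Two kinds of cutoffs exist in the package
and are deliberately distinct:

* The *cluster model* carries descriptive cutoffs obtained from the
  observed day-270 values against the cluster labels, the sorted-sweep
  rule: a value $v$ assigns $x$ to the lower (more-loss) class iff
  $x \le v$; the error-minimizing $v$ is chosen, ties resolved to the
  largest candidate, each adjacent class pair solved on its own members.
* Each trained regression model calibrates its own conversion cutoffs with
  the same sweep, but on the model's *training-set predictions*. This is a
  deliberate design choice: with cutoffs taken from observed values, the
  extreme member of each class sits exactly on its own boundary and any
  epsilon of regression error flips its class, so even a perfectly learned
  separable cohort would not reach training accuracy 1. Calibrating on
  predictions removes that fragility and is the conversion that actually
  minimizes training classification error of the *predictor*. Inside
  cross-validation the calibration uses training-fold predictions only.

`regression_to_class()` treats a prediction within about $10^{-8}$ of a
cutoff as lying on it (hence in the lower class); this numerical guard
exists because a boundary individual's predicted value can differ from its
own calibration value in the last floating-point digit.

## Applying models to partially observed individuals

Predictions for a new individual follow the rules used at validation time:

* the frame is the one whose end is closest to the last entry
  (ties to the longer frame: three and a half months of data use the
  4-month model);
* a prediction is issued only if the individual has at least two entries
  within the frame and the last in-frame entry is at most 30 days before
  the frame end;
* the series is built from in-frame entries only, interpolated to the last
  entry and then extrapolated to the frame end with the average daily
  change between baseline and the last in-frame entry;
* the three-class prediction is always reported; the five-class prediction
  only when the frame exceeds 4 months, where it is reliable enough to be
  useful.

Validation truth is defined exactly as in training: nearest cluster mean
by DTW, using the day-270 series (extrapolated from the last entry when
follow-up is truncated). The random baseline draws, per validation
individual, a class from the training class distribution; its expected
accuracy is $\sum_c p_\text{train}(c)\, p_\text{truth}(c)$, and the
simulated version (default 10,000 replicates) converges to it.

## The synthetic cohort generator

The real coaching cohorts behind the original framework cannot be
redistributed, so the package carries a generator
(`generate_cohort()`) whose defaults emulate their published statistics:
about 300 participants in the training configuration (60 per class),
36 ± 19 entries (range 3--149) over 270 days, and a validation
configuration (`sparse_mode = TRUE`) with 16 ± 16 entries (range 3--162)
and half of the individuals truncated at a random day before day 270.
Baseline weights are uniform on 75--135 kg and heights on 155--190 cm,
which keeps baseline BMI in the overweight-to-obese range the programs
target.

Each archetype is an exponential-plateau curve
$a\,(1 - e^{-d/\tau})$ -- an initial change levelling off, the shape the
outcome clusters exhibit -- with day-270 values of
-12, -7, -1.5, +1.5 and +5 percent, inside the reported class bands
(a majority of the high-loss cluster beyond 10% loss, the moderate
cluster in the 5--10% band, the insufficient cluster near zero, the gain
clusters below and above +3%). Plateau constants are 75 days for the loss
classes, 60 for the insufficient class and 150 for the gain classes.
Measurement noise is i.i.d. Gaussian per observation in percent space
(default SD 0.5% of baseline weight); unless a stress flag is set, noise
draws implying more than 1.5 kg/day between consecutive entries are
redrawn, so default cohorts pass the exclusion screen by construction and
the screen can be exercised separately with `stress = TRUE`.

What the generator does *not* emulate: behaviour change mid-intervention
(archetype curves are fixed), serially correlated self-reporting error
(noise is i.i.d.; a random-walk mode would be a natural extension),
dropout correlated with outcome, and digit-preference rounding. Passing
recovery and accuracy checks on these cohorts therefore demonstrates that
the pipeline's machinery is correct and self-consistent, not that the
published cohort-specific accuracies transfer; with the clean archetype
separation used here, synthetic accuracies sit above the published ones by
design of the null, and the qualitative patterns (accuracy growing with
follow-up, three-class easier than five-class, large margins over the
random baseline) are the meaningful comparison.

## Numerical and design notes

* **Exclusion screening.** "Fewer than two entries during the nine
  months" counts entries within the first 270 days; "data available for
  less than 270 days" is read as last-minus-first entry day, which is what
  interpolation to day 270 requires; "height of 100 cm or less" is an
  inclusive exclusion (exactly 100 cm is excluded); the daily-change rule
  is evaluated on consecutive raw entries, never on interpolated days,
  since interpolation cannot create a violation absent from the raw data.
  The medication criterion can be disabled
  (`validation_exclusion_config()`), matching validation data without
  medication records; that configuration also waives the 270-day span so
  truncated individuals can be validated through extrapolation, and
  requires an entry within the first 270 days instead.
* **Day 0** is the first weight entry; the baseline weight must come from
  an actual measurement. Duplicate same-day entries collapse to their
  mean.
* **Extrapolation** uses the baseline-to-last-entry average slope, not the
  last segment's slope, and is only applied where observations end before
  the target day; a single day-0 entry has no defined slope and is an
  error.
* **Ties.** Nearest-cluster assignment and k-means assignment break ties
  toward the lower cluster index; frame selection toward the longer
  frame; cutoff search toward the largest candidate.
* **Determinism.** All randomness (cohort generation, fold assignment,
  perceptron initialization, baseline simulation) flows from explicit
  seeds; identical seeds reproduce artifacts bit for bit. Deterministic
  learners are seeded too, which is harmless.
* **Problem sizes.** The shipped tests derive the cluster model from
  cohorts of 250--300 individuals (the training-cohort scale) and validate
  on about 185 sparse individuals; these sizes reproduce the study
  conditions while keeping a full test run in a few minutes.

## Known limitations

The three original hierarchical-clustering implementations are realized
as three linkage criteria on one DTW matrix; the original software stack
(three different DTW/clustering libraries with unrecorded settings) cannot
be reproduced exactly, and the consensus fraction is therefore not
comparable numerically. The perceptron is the weakest of the six methods
on small cohorts, consistent with the original report. Twelve-month
prediction, probability calibration, energy-balance modelling and
demographic covariates are out of scope.
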