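---
title: "Multiobjective classifier selection and stacked ensembles: methods"
author: "moostack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiobjective classifier selection and stacked ensembles: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moostack)
```

## The problem

Expression-based classification — calling a tissue sample tumor or normal
from a few dozen to a few thousand miRNA/mRNA measurements — faces two
coupled model-selection problems at once: *which* classifier (and with which
hyperparameters) suits the dataset, and *which* small subset of features
carries the signal. Filter statistics (chi-squared, signal-to-noise ratio)
answer the second question cheaply but ignore the classifier; a wrapper
search answers both but needs a principled way to trade accuracy against
feature-set size. moostack treats the whole thing as one multiobjective
optimization problem and then fuses the resulting solution set into a single
predictor by stacked generalization.

## Stage 1: NSGA-II over classifier, hyperparameters and features

A candidate solution (a *chromosome*) has three parts:

1. **classifier code** — 1 = random forest (RF), 2 = random tree (RT),
   3 = SMO (a linear-kernel SVM trained by sequential minimal optimization),
   4 = logistic regression (LR);
2. **hyperparameter slots** drawn from small per-classifier grids
   (RF: trees ∈ {10, 20, 30}, candidate features per split ∈ {0, 5, 6};
   RT: minimum leaf weight ∈ {1.0, 1.05, 1.25}, candidate features ∈
   {0, 3, 7}; SMO: box constraint C ∈ {1, 3, 8}; LR: none), where 0
   candidate features means "the learner's default heuristic",
   implemented as ⌊√p⌋;
3. a **binary feature mask** of length p (1 = feature used).

Each chromosome is scored by leave-one-out cross-validation on the training
split: the encoded learner is trained n times on n−1 samples restricted to
the masked features, the held-out predictions are pooled into one confusion
matrix, and the objective vector is

* macro-averaged precision (maximize),
* macro-averaged recall (maximize),
* number of selected features |S| (minimize).

Macro averaging weights classes equally, the appropriate convention when
tumor/normal class sizes are unbalanced. A class that is never predicted
contributes precision 0 (not NaN), keeping the objectives total.

The search is elitist NSGA-II: fast non-dominated sorting partitions the
population into ranked fronts; crowding distance (normalized neighbor gaps
per objective, boundary solutions get ∞) maintains spread; binary
tournaments on (rank, crowding) pick parents; single-point crossover acts
on the feature mask only (classifier and parameters are inherited intact);
parents and offspring are merged and truncated back to the population size
front-by-front, the overflowing front by descending crowding. Defaults
follow the study conditions the method was designed around: population 52,
50 generations, crossover probability 0.9, mutation probability 0.1.

### Mutation design

Three operator scopes are used — type 1 may change the whole string
(classifier code, hyperparameters, mask), type 2 the hyperparameters and
mask, type 3 the mask only. Every offspring draws one operator type
uniformly; within the operator each position changes independently with
probability `p_mut` (a code change redraws all hyperparameter slots from
the *new* classifier's grid, so grid validity is preserved by
construction). We deliberately interpret the mutation probability as a
per-gene rate rather than a per-string event rate: with a per-string event
rate of 0.1 and an expected single bit-flip per event, a 20-population,
15-generation run would perform only ~30 mask bit-flips in total, the
population collapses onto clones of an early good solution, and the search
cannot finish the job of shrinking the mask — in a calibration study with
one perfectly informative feature planted among 19 noise features, the
known optimum (precision, recall, |S|) = (1, 1, 1) was reached in only 2 of
8 runs. Under the per-gene rate the same budget recovers the optimum
reliably (all matched-seed runs in our checks). Per-gene mutation rates are
the textbook convention for genetic algorithms, and the operator "is
applied to a particular string at a given generation".

Empty masks (possible after crossover, mutation, or random initialization)
are repaired by setting one uniformly chosen bit, since the wrapper
objective needs at least one feature. Duplicate chromosomes are evaluated
once: LOOCV results are cached on the triple (code, parameters, mask),
which dominates runtime.

### What the front means

At termination the population is reported with ranks and crowding
distances. Rank-1 members are the non-dominated set: each is a
classifier + hyperparameters + feature subset that no other solution beats
simultaneously on precision, recall and parsimony. `unique_rank1()`
deduplicates them (identical code/parameters/mask) and orders them by
LOOCV F-measure, then by fewer features, then by first occurrence.

Search progress is summarized per generation by the rank-1 hypervolume
with respect to the reference point (precision, recall, |S|) =
(0, 0, p + 1). Because truncation is elitist, this quantity is
non-decreasing over generations; the package computes it exactly by
slicing the (integer) feature-count axis and accumulating 2-D staircase
areas.

## Stage 2: stacked generalization of the unique rank-1 solutions

Each of the N unique rank-1 solutions is fit on the full training split
(restricted to its own mask) and contributes one prediction column
P_1..P_N, appended to the feature matrix as integer class codes; the
solution with the highest stage-1 F-measure is refit as meta-learner on the
augmented training set and scored on the augmented test set. For k > 2
classes, one meta-model is trained per class on one-vs-rest 0/1 labels and
a sample is assigned to the class whose model yields the highest positive
score (ties to the lowest class code); with two classes the single binary
meta-model is used directly, and the one-vs-rest path reduces to it.

**Training-set augmentation is out-of-fold by default.** The base models'
*in-sample* training predictions are a trap: a memorizing learner (RF/RT)
reproduces the training labels exactly, so its prediction column looks like
a perfect separator to the meta-learner even when the base is useless at
test time — we observed an RF meta-learner splitting on exactly such a
column first and dropping to 0.45–0.80 test accuracy while its best base
scored 1.0. The default therefore augments the training set with each
base's LOOCV predictions (the standard Wolpert-style construction, and
consistent with how stage 1 scores solutions); test-set columns always come
from bases fit on the full training split. The literal in-sample variant
remains available (`train_augmentation = "insample"`).

The meta-learner sees all original features plus the N prediction columns
by default (`meta_features = "all"`); `"mask+preds"` and `"preds_only"`
restrict it.

## Preprocessing filters

Two filter paths are provided for wide matrices, both fit on the training
split only (leak-free) and then applied to both splits; fitting on the
union is available as an explicit escape hatch (`fit_on = "all"`).

* **Chi-squared top-k**: each feature is discretized (features with at most
  `n_bins` distinct values are used as-is; continuous features get
  `n_bins = 10` equal-frequency quantile bins), the χ² statistic of
  independence against the class label is computed without continuity
  correction, and the k highest-scoring features are kept (ties by
  ascending feature index; a constant feature scores 0).
* **SNR filter** (two-class only): after per-sample standardization (each
  row to mean 0, unit sample variance), each feature gets the Golub
  signal-to-noise statistic SNR = (μ₁ − μ₂)/(σ₁ + σ₂) with per-class
  sample standard deviations (denominator n−1); features with |SNR| at or
  above the mean of all |SNR| values are retained. A feature with
  σ₁ + σ₂ = 0 gets SNR 0 with a warning rather than an error.

## Data model and splitting

Datasets are samples × features numeric matrices with a label column;
labels are read as strings and coded by sorted label order, so class codes
do not depend on file row order. The stratified splitter assigns
round-half-up(`train_fraction` × count(c)) samples of every class c to the
training set (default 0.6), the remainder to the test set, clamped so both
sets retain every class; the per-class training proportion therefore
deviates from the target fraction by less than 1/count(c). The writer emits
17 significant digits so write-then-read round-trips are bit-exact.

## The synthetic generator

`synth_dataset()` draws class-conditional Gaussians: informative feature j
in class c has mean (c − 1) × `effect_size` and all features have standard
deviation `noise_sd`; noise features have mean 0 in every class. Feature
names mark ground truth (`inf_1..`, `noise_1..`). This emulates the
structure the method assumes — a small set of mean-shifted markers among
many irrelevant features — and nothing more: no heavy-tailed or count
noise, no feature correlations, no batch effects, no class imbalance.
Passing tests on it demonstrates that the search, the objectives and the
ensemble behave correctly on data satisfying the model's assumptions; it
says nothing about robustness to the distributional quirks of real
expression matrices. `synth_perfect_feature()` plants one noise-free
feature equal to the class code, giving a search problem whose optimum
(1, 1, 1) is known exactly.

Default generator conditions used across the test-suite studies: 25
samples per class (matching a ~50-sample two-class expression study),
unit noise, effect sizes 3 (moderate separation) or 6 (clear separation),
and 12–30 features with 1–5 informative. Stage-1 budgets in the bundled
studies are scaled to the problem (population 10–20, 4–15 generations);
the package defaults (52 × 50) remain the recommendation for real data.

## Numerical and degenerate-case choices

* **Seeding.** One user seed fans out to per-stage child seeds via a fixed
  integer congruence (`derive_seed()`), and every LOOCV fold fit gets a
  seed derived from (stage seed, fold index); all fits restore the caller's
  RNG stream. Reruns with the same config and seed are byte-identical in
  `front.json` and `report.json`.
* **Logistic regression** uses a ridge penalty of 1e-4. Unpenalized ML
  logistic regression is ill-posed on separable data — the fit direction
  is whatever the optimizer stops at and was observed to load on noise
  columns; a tiny ridge restores a well-defined large-margin-like solution
  and matches mainstream defaults.
* **RT mapping.** The "minimum total weight of instances in a leaf" grid
  values (1.0, 1.05, 1.25) are mapped to a minimum node size of
  ⌈weight⌉ on a single unbagged randomized tree (one tree, no bootstrap,
  `mtry` = the chosen candidate-feature count).
* **Dominance and ties.** Equal objective vectors are mutually
  non-dominating and share a rank. Tournament ties on (rank, crowding) are
  broken uniformly at random; truncation ties within the overflow front by
  original index.
* **Crowding** normalizes each objective by its range within the front; a
  zero range contributes 0; fronts of size ≤ 2 are all-boundary (∞).
* **Degenerate folds.** A LOOCV training fold that has lost all but one
  class yields a constant predictor of that class rather than an error.

## Known limitations

* LOOCV wrapper evaluation is O(n) model fits per candidate; the design
  assumes the small-n / moderate-p regime of expression studies. For large
  n a k-fold objective would be the natural extension.
* The stage-2 meta-learner inherits the base grids; no meta-specific
  tuning is performed.
* The chi-squared filter's equal-frequency binning is one of several
  discretization conventions; scores (not selections) can differ from
  entropy-based binning implementations.
* The generator's Gaussian equal-variance model is favorable to the SNR
  statistic by construction; rankings on real, skewed expression data will
  be noisier than the tests suggest.
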