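---
title: "Adaptive shortening of the Berg Balance Scale: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive shortening of the Berg Balance Scale: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ebbs)
```

## The problem

The Berg Balance Scale grades fall risk in older adults from 14 motor tasks,
each scored 0–4 by a physiotherapist; the 0–56 total is banded into high
(0–20), medium (21–40) and low (41–56) risk. The band, not the exact total,
drives the clinical decision (referral to a fall-prevention programme), and
the band is heavily over-determined by 14 scores: a handful of informative
tasks usually pins it down. `ebbs` exploits that redundancy to shorten the
assessment, administering tasks one at a time and stopping once an ensemble
classifier is sufficiently confident of the band.

## The predictor bank

For a task subset $SS$, the bank trains a random forest (default 100 trees,
depth capped at 10 — an ensemble size at which vote shares resolve to a 0.01
grid, and a depth that saturates trees on ≤14 ordinal features without
letting single leaves memorise subjects) to predict the risk band from only
the scores in $SS$. Training uses the subjects with no missing score in
$SS$; subjects are dropped per subset rather than imputed, because per-task
missingness (unperformable tasks, recording faults) is a first-class feature
of real BBS tables. The predictor's *confidence* on a score vector is the
modal vote share of the ensemble, a natural [1/3, 1]-valued statistic for a
three-class forest; ties between vote counts are resolved toward the
higher-risk band, the conservative direction for a screening instrument.
`train_accuracy` and `mean_confidence` are computed over the subset's own
training subjects, matching the selector objectives below, which index the
training set; generalisation estimates come from the evaluation module's
per-fold retraining, never from these in-sample figures.

Banks cache predictors by subset. Eager enumeration of all $2^k - 1$ subsets
is supported for small batteries (and refused above $k = 16$); the default is
lazy train-on-demand, since a greedy session only ever touches
$O(k)$ subsets per step. Per-subset training seeds are derived from the
master seed and the subset membership by a polynomial hash, so lazy and
eager enumeration — and re-runs on another machine — train bit-identical
forests. Degenerate subsets (single risk class among complete subjects) fall
back to a constant predictor with confidence 1, with a logged message.

## Selector rules

With $CSS$ the administered subset, $UT$ the unused tasks, and $(x_i, y_i)$
the training pairs, the next task maximises a weighted count of training
subjects the augmented predictor classifies correctly. Method 1 uses the
plain count; method 2 keeps only subjects still "undecided" at threshold
$CT$ (strict inequality $\mathrm{Conf}(CSS, x_i) < CT$, exactly as the
objective is stated); method 3 weights each subject by the Gaussian kernel
$\exp(-\lVert CSS(x_i) - CSS(x_p)\rVert^2 / \sigma^2)$ of its similarity to
the patient; method 4 additionally drops subjects the all-task predictor
misclassifies. Two open design points are resolved as follows:

* **Domain of the sums.** Each candidate's sum runs over the training
  subjects complete on $\{CSS, T\}$ — the same population its predictor was
  trained on. Method 4 additionally requires $\hat y_i$ from the all-task
  predictor, so its sum is restricted to subjects complete on the whole
  battery (those $\hat y_i$ are computed once per bank and cached).
* **Annihilated objectives.** If the weights zero out every candidate's sum
  (e.g. no training subject sits below $CT$), the selector falls back to the
  method-1 objective and logs the event, rather than making an arbitrary
  pick.

Ties in the argmax go to the lowest standard task number, for
reproducibility. `sigma2 = "auto"` uses the median pairwise squared distance
between training restrictions to $CSS$, recomputed each step and floored at
$10^{-6}$; the median heuristic keeps the kernel informative across the
shrinking score space without a tuning run.

## Sessions and stopping

A session seeds with an initial subset (sizes 1–3 are typical; the greedy
selectors are myopic, so a globally optimal small subset — the best-ranked
subset of that size — mitigates early local optima), then alternates
predict → select → administer. Prediction only ever sees administered
scores; the subject's remaining scores are read on demand, preserving the
semantics of a simulated clinical administration (a missing requested score
raises an error carrying the partial trace). Stopping compares confidence to
$CT$ with $\geq$ by default — with 100 trees, confidence 1.00 is attainable
and $CT = 1$ must be able to stop — and `stop_rule = "gt"` is available for
the strict reading. When $CT$ is never reached the session reports the final
(largest-subset) prediction with `stop_reason = "tasks_exhausted"`.

## Evaluation

`crossval_curve()` runs stratified $k$-fold cross-validation (default 5
folds). Every trained component — the bank, the method-4 $\hat y_i$, and the
initial subset when given as a size — is rebuilt from the training split of
each fold; held-out subjects (those with complete score vectors, so that any
requested task can be administered) are run through full adaptive sessions.
Accuracy is pooled over held-out predictions rather than averaged per fold;
the pooled truth/prediction pairs are returned so the confusion matrix and
the curve agree by construction. The short-form comparator (`sfbbs_cv()`)
evaluates the single 7-task subset predictor under the same folds; its
membership is user configuration, since the published short form is defined
outside this package, and its scores stay on the 0–4 scale. Occurrence
matrices summarise where each task lands in the produced sequences; their
column sums equal the fraction of sessions reaching each position and are
non-increasing.

For the full-battery comparator the package follows the standard recipe for
final-band classification from 14 scores: an RBF-kernel SVM with
$\gamma = 1/n_f = 1/14$ and $C = 3$, leave-one-out or stratified $k$-fold
cross-validated. Its per-class scores — one-vs-one vote fractions — feed
`adjust_thresholds()`, which predicts the highest-risk band whose normalised
score reaches $\tau$ and otherwise the modal band: lowering $\tau$
monotonically trades false positives for fewer missed high-risk subjects.
The ordinal MSE codes the bands high = 0, medium = 1, low = 2, so an
adjacent-band error contributes 1 and a high/low swap 4. ICC uses the
two-way mean-squares decomposition, single measure; the consistency form
ICC(3,1) is the default (reliability of raters who may differ by a constant
offset), with the absolute-agreement form switchable, and a conservative
MIN-of-two-raters column is available via `rater_table()`.

## The synthetic cohort generator

No clinical BBS table ships with the package, so the generator is the study
bed. It emulates the structure such cohorts show: per-subject scores driven
by one latent balance ability, tasks of widely varying difficulty with score
distributions piling up at 4 on easy tasks, three risk bands with low-risk
subjects outnumbering high-risk ones, and per-task missingness. Scores are
binomial-logistic: task $t$ of a subject with ability $\theta$ scores
$\mathrm{Binomial}(4,\ \mathrm{logistic}(a_t(\theta - b_t)))$. This model
was chosen over a graded-response model because its closed-form mean
$4\,\mathrm{logistic}(a_t(\theta - b_t))$ makes the generator itself
testable against Monte-Carlo tallies, and its expected scores are provably
monotone in ability.

The frozen default profile (`default_bbs_profile()`):

* difficulties $b$ = (−2.5, −1.8, −4.0, −2.3, −1.2, −1.5, −1.0, −0.8, −1.0,
  −0.6, 0.6, 1.2, 1.4, 1.6): task 3 (sitting unsupported) minimal, so it is
  almost always scored 4; the stepping/single-leg tasks 12–14 maximal;
* discriminations $a \approx 1$ (0.8–1.2), ordinary single-factor loading;
* ability mixture: weights 0.15/0.35/0.50, means −2.7/−0.7/+1.5, sds
  0.6/0.55/0.7, placing expected totals near 12, 30 and 47 — the centres of
  the three bands — and giving all three bands with low > high prevalence,
  as in a screening population enriched with ambulatory controls;
* `missing_rate` 0.05 per task, a light rate of unperformed tasks.

Risk labels are computed from the pre-masking totals and only then is
missingness applied, so stored labels are always sum-consistent. All
randomness flows through one seed in the configuration; equal configurations
generate bitwise-equal cohorts.

What passing on this generator does **not** show: real BBS scores are
ordinal ratings with rater effects, residual inter-task correlation beyond
one latent factor, and missingness that is informative (harder tasks are
skipped by frailer patients). The generator's single-factor, independent-
masking world is friendlier to subset prediction than clinical data, so
accuracies and session lengths here bound the idea's behaviour, not a
clinic's.

## Problem sizes and numerical choices

Exhaustive oracle checks (brute-force selector objectives, ranking sorts,
vote tallies) run on a 4-task, 12-subject toy battery where all $2^4 - 1$
predictors can be enumerated. The headline synthetic experiment uses 300
subjects, 5 stratified folds, selector method 3, $CT = 0.96$, and a size-3
per-fold-optimized initial subset; at that size the adaptive battery's
pooled accuracy tracks the full-battery SVM within a few points at roughly
half the tasks, and the whole experiment runs in about a minute on one core.
Confidence comparisons use exact floating-point thresholds (vote shares are
exact multiples of 1/ensemble_size); objective argmaxes use exact
comparisons with the lowest-task-number tie-break.

## Known limitations

* Greedy, one-step-lookahead selection; no cost weighting of tasks.
* Subjects with missing scores are excluded from held-out session
  simulation (a session cannot administer an unscored task), so evaluation
  conditions on completeness.
* Vote-share confidence is not a calibrated probability; $CT$ is a tuning
  knob, not a coverage guarantee.
* The bank is rebuilt (deterministically) rather than serialised; for the
  14-task battery with lazy enumeration this is cheap, but eager enumeration
  of all 16,383 subsets at 100 trees is deliberately gated.
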