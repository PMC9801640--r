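---
title: "Hybrid resampling for imbalanced clinical tables: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid resampling for imbalanced clinical tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical prediction tables are routinely imbalanced: one outcome class
outnumbers the other several-fold (the shapes this package emulates are a
249/112 missed-abortion table with 7 features and a 500/268 diabetes table
with 8 features). A classifier trained on such data buys overall accuracy by
sacrificing the minority class, which is exactly the class a diagnostic tool
must not miss. Two families of remedies exist: over-sampling, which
synthesises minority rows, and under-sampling, which removes majority rows.
`hybridsample` implements both and — its central object of study — their
composition: SMOTE followed by an edited-nearest-neighbour (ENN) cleaning
pass.

```{r, eval = FALSE}
library(hybridsample)
ds <- preset_dataset("diabetes_like", seed = 1)
rs <- smote_enn(ds, resampler_config(seed = 1))
rs
```

## The resamplers

**SMOTE.** For a minority seed row $x_i$ with minority-class
$k$-nearest neighbours $x_{ik}$ (Euclidean distance, $k$ = 5 by default), a
synthetic row is
$$x_{new} = x_i + r\,(x_{ik} - x_i), \qquad r \sim U(0,1),$$
a uniformly drawn point on the segment between seed and neighbour. Seeds are
cycled round-robin in row order and the neighbour is drawn uniformly from
the $k$, until the minority count reaches
`round(target_ratio * majority)`; with the default `target_ratio = 1` the
classes balance exactly (500/268 becomes 500/500). One published rendering
of this formula carries the difference with the opposite sign,
$x_i + r\,(x_i - x_{ik})$, which *extrapolates away* from the neighbour and
contradicts the accompanying description of synthesis *between* the two
points; we treat the sign as a typo and interpolate. The
`strict_eq4 = TRUE` switch reproduces the extrapolating variant for
comparison.

**ENN.** Every eligible row whose label disagrees with the majority vote of
its `k_enn` (= 3) nearest neighbours — self excluded, neighbours drawn from
the whole dataset — is marked, and all marked rows are deleted *together* in
one simultaneous pass. Simultaneous marking makes the deletion set
independent of row order, which sequential deletion is not. Vote ties (even
`k_enn`) retain the row; a `unanimity` switch requires all neighbours to
disagree before deleting.

**Which class ENN edits.** Published count trajectories are asymmetric:
standalone ENN shrinks only the majority (e.g. 249/112 to 219/112), while
the SMOTE-ENN hybrid shrinks both classes (to 114/49 on the same table).
`edit_target` therefore defaults to `"majority_only"` in standalone `enn()`
and to `"both_classes"` inside `smote_enn()`, matching both behaviours; the
narrative around these procedures alternates between deleting noise "in the
majority" and "in the minority", and the explicit switch resolves that
ambiguity operationally rather than by guessing intent.

**Tomek links.** A pair of opposite-class rows that are each other's
*single* nearest neighbour straddles the class boundary; the majority-class
member of every link is deleted. The source study names this sampler
without defining it, so the standard definition is adopted.

**Hybrids.** `smote_enn()` and `smote_tomek()` are literal compositions:
the editing stage runs on the post-SMOTE dataset, origin tags
(original/synthetic) survive, and deleted indices refer to the intermediate
dataset. Tests assert exact row-set equality with calling the two stages in
sequence.

**Determinism.** One user seed feeds every stochastic component through
independently derived streams (`derive_seed`), so adding a stage never
perturbs another stage's draws; distance ties always break by ascending row
index. All resamplers are bit-reproducible under a fixed seed.

**Scaling.** Distances are computed on raw feature values by default — the
procedures we follow are silent on scaling, and fidelity wins — but
`nearest_neighbors(..., scale_minmax = TRUE)` provides min-max scaling for
data whose features live on very different ranges (glucose vs. age).

## Classifiers

The published experiments use Weka's C4.5/Randomtree/Reptree; reproducing
those dialects is out of scope, and their role is played by a single
CART-style tree: greedy top-down induction minimising weighted Gini
impurity, thresholds at midpoints of adjacent observed values, stopping at
`max_depth`, purity, `min_samples_leaf`, or when no split strictly reduces
impurity. Weighted training uses the weights directly in the impurity
computation (not weight-proportional resampling), which keeps AdaBoost
exactly reproducible. Candidate-feature ties break toward the lower feature
index and threshold ties toward the smaller value — deterministic,
seed-free rules.

Three standard combiners sit on top:

* **Bagging** — $T$ bootstrap resamples of size $n$, one tree each,
  unweighted vote;
* **AdaBoost.M1** — sequential reweighting with
  $\beta_t = \epsilon_t/(1-\epsilon_t)$, misclassified-row weights
  multiplied by $1/\beta_t$ and renormalised, member vote weight
  $\ln(1/\beta_t)$; a perfect round is kept with a capped large weight and
  stops training, and a round with $\epsilon_t \ge 0.5$ is discarded (at
  round one this degenerates, flagged, to the majority-class predictor);
* **Random forest** — bagging plus a fresh random $m$-subset of features at
  every split, $m = \lceil\sqrt{p}\rceil$ by default.

$T$ is never stated in the source experiments; the package default is 100,
exposed everywhere. Ensemble vote ties break toward the positive class so
that sensitivity is never silently sacrificed — a documented, testable
choice. The positive-class score of an ensemble is its weighted
positive-vote share.

## Evaluation

Metrics are computed from the confusion counts of an *explicit*
`positive_class` (the disease class). The source text defines TP against
"the majority" while simultaneously calling the quantity minority
sensitivity; rather than imitate that internal inconsistency we surface the
choice as a parameter. Sensitivity $TP/(TP+FN)$, specificity $TN/(FP+TN)$,
precision $TP/(TP+FP)$, F-measure (harmonic mean), and
$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TN+FN)(TN+FP)(TP+FN)(TP+FP)}}$$
follow the standard forms; any $0/0$ returns 0 and is flagged, keeping
result tables total. AUC is the rank-based (Mann–Whitney) statistic with
half credit for ties. Note that swapping which class is called positive
leaves MCC unchanged (it swaps $TP\leftrightarrow TN$ and
$FP\leftrightarrow FN$); inverting the *predictions* negates it.

**Cross-validation.** The headline protocol resamples the whole dataset
once and then runs stratified ten-fold CV on the resampled data
(`mode = "paper_faithful"`). This is what the source experiments describe,
and reproducing them is the point — but synthetic rows interpolated from
training-fold neighbours then appear in test folds, an optimistic leak. The
`"leakage_safe"` mode resamples inside each training fold only and
evaluates on untouched test folds; expect materially lower numbers there.
Both modes coincide exactly when no resampler is used. Fold assignment
shuffles within class and deals rows cyclically, starting each class where
the previous one stopped, so overall fold sizes differ by at most one (361
rows in ten folds gives sizes 36/37) and per-fold class ratios stay within
one row of the global ratio.

## Statistical comparison

**Wilcoxon signed-rank.** Differences of paired metric vectors are ranked
by absolute value (zeros dropped, ties averaged), signs reattached, and
$T = \min(R^+, R^-)$ compared against a small-sample two-sided critical
value. The study this package follows rejects at $T \le 2$ for $n = 6$,
$\alpha = 0.05$, although the standard two-sided table gives 0 there; with
`follow_paper = TRUE` (default) the tabled convention is used so the
published pairwise table reproduces, and the standard-table decision plus
an exact enumeration p-value are always reported alongside. The exact null
distribution is computed by dynamic programming over the (possibly tied)
ranks, and tests check it against full $2^n$ sign-flip enumeration.

**Friedman.** With $N$ metric rows and $k$ algorithms, average ranks $R_j$
give
$$\chi^2_F = \frac{12N}{k(k+1)}\Big[\sum_j R_j^2 - \frac{k(k+1)^2}{4}\Big],
\qquad F_F = \frac{(N-1)\,\chi^2_F}{N(k-1) - \chi^2_F},$$
with $F_F = +\infty$ (and rejection) when the chi-square saturates at
$N(k-1)$. Two F critical values are reported: the exact one at
$(k-1, (k-1)(N-1))$ degrees of freedom and the $(k, k(N-1))$ convention
used in the published worked computation (1.917 at $k=12$, $N=6$); at the
magnitudes involved the decision never differs. The published arithmetic
rounds average ranks to two decimals before the chi-square and the
chi-square to two decimals before the F transformation; `digits = 2`
reproduces that pipeline exactly (57.69 and 34.71 on the random-forest
table, 30.45 and 49.28 on the Adaboost and Bagging tables — the latter two
printed values are the $F_F$ statistics). With `digits = NULL` full
precision is carried instead.

## The synthetic-data generator

No generative model is published for the clinical tables, so the generator
emulates only what the algorithms consume: shape, imbalance, and planted
structure. Two spherical unit-variance Gaussian clusters sit `class_sep`
apart along the first axis (2.0 in the presets — moderate overlap).
Exactly `round(boundary_frac * n)` rows are redrawn around the midpoint
(sd 0.5), emulating boundary samples; exactly `round(noise_frac * n)`
further rows are *mislabeled* — their features are drawn from the opposite
class's cluster while their label is kept. Planting noise by opposite-cluster
placement rather than by label flipping keeps the class counts exactly
`n_maj`/`n_min`, which the preset contracts require; structurally the two
are the same thing (a label that disagrees with the point's position).
Counts are fixed rather than binomial so tests can assert them exactly, and
all planted indices ship in a provenance attribute.

What the generator does *not* emulate: the real features' marginals,
covariance, integer codings or units. Passing tests therefore demonstrate
algorithmic correctness and the qualitative behaviour of the samplers on
cluster-structured data, not clinical performance on the private tables.

## Numerical choices and problem sizes

* Split gains must exceed $10^{-12}$ for a split to be accepted; identical
  feature rows with mixed labels become a majority leaf.
* SMOTE collinearity in tests is asserted to $10^{-9}$.
* CSV output carries 17 significant digits, so write/read round-trips are
  bit-lossless.
* An editing pass that empties a class sets a warning flag instead of
  erroring, and the resampled object records it.
* The test suite runs at desk scale: oracle equivalences on random
  instances up to 300 rows, the planted-noise recovery study over 20 seeds
  of a 200/100 table at `class_sep = 6`, and the headline-effect study over
  10 seeds of a 500/100 overlapping table (`class_sep = 2`, 5% noise) with
  25-tree forests of depth 8 under ten-fold CV. These sizes were chosen
  once as representative desk-scale conditions for a laptop-class machine.

## Known limitations

* Binary classification only; multiclass voting and categorical-feature
  distances are out of scope.
* The comparator samplers that the source study only cites
  (Borderline/Adasyn/ANS/Gaussian/k-means/Cure SMOTE, instance-hardness and
  radial-based under-sampling) are not implemented; their published results
  are shipped as read-only fixture tables for the comparison machinery.
* `paper_faithful` cross-validation is optimistically biased by design (see
  above); use `leakage_safe` for honest generalisation estimates.
* The AdaBoost weak learner is the same CART tree as everywhere else, not a
  Weka Randomtree; published absolute numbers are not expected to
  reproduce from re-training, and the package does not claim them — its
  verbatim fixtures exist precisely so the statistical-comparison layer can
  be validated against published arithmetic.
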