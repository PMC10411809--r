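---
title: "Certainty-sampling active annotation: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Certainty-sampling active annotation: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(healr)
```

## The problem

Pool-based active learning assumes a small labelled seed set `X` and a large
unlabelled pool `U`, and iterates: train a classifier on `X`, use a query
strategy to pick a batch from `U`, obtain labels for the batch, move it into
`X`. Classical strategies (uncertainty sampling, random sampling) need a
human expert to label every queried batch. In settings where labels come
from literature curation or wet-lab experiments — the motivating case is
annotating conditionally essential genes, where only a few hundred positives
are known against >10,000 unlabelled genes — that expert is the bottleneck.

`healr` implements the alternative this package is built around:
**certainty sampling with a heuristic label source**. Instead of querying
the samples the classifier is least sure about and asking a human, it
selects the samples the classifier is *most* sure about and lets the
classifier's own prediction stand as the label (a pseudo-label). The wager
is that with a sufficiently strict, dynamically chosen confidence cut-off,
pseudo-labels are nearly as reliable as expert labels and cost nothing.

## The heuristic component

Each iteration the trained classifier assigns every pool sample a
positive-class probability. The heuristic then:

1. **Partitions** the scored pool at the classification `boundary`
   (default 0.6): scores `>= boundary` form the provisional positives
   `P+`, the rest `P-`. The boundary sits above 0.5 deliberately: with a
   0.5 cut the positive side collects too many borderline samples and the
   false-positive rate of the pseudo-labels rises.
2. **Computes quartiles** of each side by the `(i/4)(n+1)`-th-term rule
   (`heal_quartile()`): the quartile is the order statistic at position
   `(i/4)(n+1)`, linearly interpolated at fractional positions and clamped
   to `[1, n]`. This is the plotting position of `stats::quantile(type =
   6)`; the package carries its own implementation because the rule is part
   of the method's definition, and cross-checks it against `quantile()` in
   the tests.
3. **Sets the positive cut-off** `sup`. The top-quartile members of `P+`
   are the scores `>= Q3(P+)` (inclusive, so the set is never empty when
   `P+` is non-empty). If the smallest of them exceeds the user `threshold`
   (default 0.9), `sup` is that minimum — the cut-off adapts upward when
   the classifier is very confident; otherwise `sup = threshold`. Samples
   scoring `>= sup` are pseudo-labelled positive. Consequently **no
   pseudo-positive ever has a score below `threshold`**.
4. **Sets the negative cut-off** `inf = max` of the bottom-quartile members
   of `P-` (scores `<= Q1(P-)`). Samples scoring `<= inf` are
   pseudo-labelled negative. There is deliberately *no* user threshold on
   the negative side: the asymmetry is part of the method (negatives
   dominate the motivating data, so the bottom quartile is already deep in
   safe territory).

The batch is the union of both sides; it can be empty, and its size is
cut-off-driven rather than fixed. The loop (`run_heal()`) stops when the
labelled fraction reaches `stop_fraction` (default 90%), when the batch is
empty (`status = "stalled"`), or after `max_iterations`.

### Stalling

An empty batch would loop forever, so it terminates the run with
`status = "stalled"`. The optional `stall_fallback = "top1"` instead
force-adds the single highest- and lowest-scoring samples, trading
label-quality guarantees for progress; it is off by default because a stall
usually means the classifier cannot currently clear the 0.9 bar and its
pseudo-labels would be exactly the ones not to trust.

## Per-iteration preprocessing

Two stages run inside every iteration, on the current labelled set only:

* **SMOTE class balancing** (`smote_balance()`): synthetic minority samples
  are convex combinations `x + u (x_nn - x)`, `u ~ U(0,1)`, of a real
  minority sample and one of its `k = 5` minority nearest neighbours
  (`k` capped at minority size − 1). Synthetic rows exist only for the
  classifier fit of that iteration: they are regenerated from real rows
  each time and never enter the labelled set permanently, so synthetic
  points cannot compound across iterations.
* **Permutation-importance feature selection** (`select_top_features()`):
  a bootstrap random forest is fit, and each feature's importance is the
  out-of-bag accuracy of the baseline model minus the accuracy after
  permuting that feature (via `randomForest::importance(type = 1, scale =
  FALSE)`). The top `top_k_features` (default 400) are kept. When the data
  has no more than `top_k_features` columns the ranking cannot drop
  anything and the forest fit is skipped.

Two stages run **once up front** on the union of labelled and pool rows
(`preprocess_dataset()`), because they are estimates of the data
distribution rather than of the current model: z-score normalisation
(sample sd, `n−1` denominator; constant columns map to zeros) and the
Pearson redundancy filter (`correlation_filter()`), which examines pairs in
descending `|r|` and, whenever a pair exceeds `corr_cutoff = 0.70` with
both members still retained, drops the one whose correlation with the class
labels is weaker (ties keep the earlier column; zero-variance features have
their correlations defined as 0 and are never dropped by the filter). The
greedy descending-`|r|` order makes the outcome deterministic and
order-invariant.

## The classifier and its hyperparameters

The base learner is a gradient-boosted decision-tree ensemble (xgboost,
histogram method, leaf-wise growth capped at `num_leaves`). Defaults
(`default_classifier_params()`): 600 trees, learning rate 0.05, 32 leaves,
`colsample_bytree` 0.2, L1 = 3, L2 = 1, minimum split gain 0.01, and
`min_child_weight = 40`.

One of these deserves a warning. `min_child_weight` is a **floor on the
summed hessian of a leaf**, and for logistic loss each row contributes at
most 0.25. A floor of 40 therefore requires roughly 320 rows per leaf
before any split is permitted: appropriate for the thousands-of-samples
regime these defaults were tuned in, but on a few hundred rows the booster
degenerates to a constant 0.5 score, and even at `n = 400` the probability
range stays inside `[0.24, 0.75]` on perfectly separable data — below the
0.9 certainty threshold, so the heuristic would never select a positive.
All desk-scale examples, tests and the acceptance script in this package
therefore run with `classifier_params = list(min_child_weight = 2)`; every
other hyperparameter keeps its default. Users with large data sets should
keep the default 40.

Per-iteration 5-fold stratified cross-validation scores
(accuracy/precision/ROC-AUC) are recorded in the run history for
monitoring; they are reporting-only (the deployed model is refit on the
full balanced set) and can be disabled with `cv_folds = 0`, which the
longer simulations do for speed. After the loop ends the returned
classifier is refit on the complete final labelled set, since the in-loop
model never saw the last accepted batch.

## Benchmarking against oracle strategies

`run_benchmark()` reproduces the comparison protocol: a stratified 20% of a
fully labelled data set keeps its labels, the remaining 80% becomes the
pool with labels held back, and the chosen strategy runs to the 90% stop
rule. Uncertainty sampling (batch of 20 nearest `|score − boundary|`) and
random sampling (uniform batch of 20) have each batch corrected by a
simulated oracle that returns the held-back truth; certainty keeps its own
pseudo-labels.

Two metric sets are reported, and they answer different questions:

* `metrics_annotation` — are the labels assigned during the run correct?
  This is the direct measure of annotation quality, the quantity the
  framework exists to maximise.
* `metrics_residual` — how does the final classifier do on the samples
  still unlabelled at stop?

These must not be compared casually across strategies: the residual pool of
an oracle strategy is a near-uniform sample of the data, whereas the
certainty strategy's residual pool is *by construction* the samples the
classifier never became confident about — an adversely selected test set.
On well-separated synthetic data the oracle strategies' residual accuracy
saturates at 1.0 while certainty is evaluated only on its own hardest
cases, so certainty can trail on `metrics_residual` even when its
annotation agreement is indistinguishable from the oracle's. The package
reports both and labels them distinctly.

## Gene-set feature engineering

For the functional-genomics use case, features are built from curated gene
sets and a protein-association network:

* Redundancy between sets is the Jaccard similarity `J(A,B) =
  |A∩B| / |A∪B|`; pairs with `J > 0.3` (strictly — "above" is read
  literally) become edges of a redundancy graph.
* Each set carries weight `w = 1 − log10(p)/100` from its significance
  p-value (strictly decreasing in `p`, ≥ 1 on `(0,1]`).
* `select_nonredundant()` keeps the maximum-weight independent set of the
  redundancy graph: maximise `Σ w_i X_i` subject to `X_i + X_j ≤ 1` on
  every edge, `X_i ∈ {0,1}`. The binary program is solved exactly by
  branch-and-bound (branch on the highest-degree remaining vertex, prune
  with the remaining-weight bound); the tests verify optimality against
  exhaustive enumeration.
* The enrichment feature of gene `g` against set `S` is `−log10` of the
  one-sided Fisher's exact p-value comparing `g`'s network neighbourhood
  with `S` over the gene universe (default: union of network genes and all
  set members). One-sided, because enrichment features are directional by
  construction. An empty neighbourhood yields 0 (`p = 1`) by convention.

## What the synthetic generator does and does not emulate

`make_binary_dataset()` draws two Gaussian clusters: each informative
dimension is mean-shifted by `class_sep` standard deviations between
classes ("separated by `class_sep` along informative dimensions" — so the
overall Mahalanobis separation grows with the number of informative
dimensions), plus pure-noise and correlated-copy dimensions, with class
imbalance `pos_fraction` (default 0.35, matching the imbalance typical of
the clinical benchmark tables and of essentiality labels). Defaults are
`n = 200`, 10 features of which 5 informative. `make_geneset_fixture()`
plants controlled Jaccard structure (a redundant pair, a 3-clique, or
disjoint sets), log-uniform p-values on `[1e-10, 1]`, and a network in
which one gene's neighbourhood equals one set exactly.

These generators produce what the method *assumes*: unimodal Gaussian
classes, independent noise, exactly calibratable redundancy. Real tabular
data has multimodal classes, heteroscedastic and heavy-tailed features,
label noise, and missingness; passing tests on the generators therefore
demonstrate correctness of the machinery and the qualitative behaviour of
the method (pseudo-label fidelity rising with separation, strategies
ordered as expected on agreement), not performance guarantees on any real
data set.

## Numerical choices and tie-breaks

* Quartile membership is inclusive (`>= Q3`, `<= Q1`), so extreme-quartile
  sets are non-empty whenever their side is; partitions with fewer than 4
  samples use the same clamped formula (`n = 1` returns that value).
* Selection ties and batch ordering are resolved by ascending sample ID;
  random draws go through seeded RNG with per-iteration seeds derived
  deterministically from `(seed, iteration, stage)`, so runs are bit
  reproducible and iterations are independent.
* Missing feature values are rejected at ingestion by default
  (`missing = "mean_impute"` opts into column-mean imputation); labels may
  be arbitrary strings, mapped to 1 by `positive_label` and 0 otherwise.
* z-scores use the sample (n−1) standard deviation; constant columns map
  to zeros rather than NaN.
* ROC-AUC is the Mann-Whitney rank statistic with midranks (ties get half
  credit); precision is reported absent when there are no positive
  predictions, AUC absent when the truth is single-class.

## Problem sizes in the test suite

The test and acceptance runs use the sizes the method's contracts are
stated at: 1000 random score pools of up to 200 samples for the heuristic
equivalence check, `n = 200` synthetic runs across separations
{3, 2, 1, 0.5}, 20 paired seeds for the strategy comparison, 200 random
graphs of up to 18 vertices for the exact-solver check, and every
contingency table over universes up to 30 genes for the Fisher feature.

## Known limitations

* Pseudo-labels enter the training set with full weight and are never
  revisited; an early mistake can propagate (confirmation bias inherent to
  self-training).
* The certainty batch has no size cap, so a single iteration can absorb a
  large fraction of the pool when the classifier is confident.
* The heuristic's negative side trusts the bottom quartile unconditionally;
  on data where negatives are rare or poorly modelled this is the likelier
  source of label noise.
* The exact independent-set solver is exponential in the worst case; it is
  comfortable at curated-collection sizes (hundreds of sets, sparse
  redundancy) but not intended for dense graphs with thousands of
  vertices.
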