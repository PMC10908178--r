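---
title: "Few-shot gene subset selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Few-shot gene subset selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The PAM50 signature assigns breast tumours to the four intrinsic molecular
subtypes (Basal-like, HER2-enriched, Luminal A, Luminal B) from the
expression of 50 genes. Measuring 50 genes is costly in assay design and in
clinical workflows, and several of the 50 are of debated relevance. This
package implements a *wrapper* strategy for shrinking such a signature:
draw many uniform random subsets of the signature, score each subset by how
well a linear classifier trained on it recovers the subtypes, keep the best
subset of every size, and then judge those winners on an independent cohort
that played no role in the selection.

`fewshotgenes` provides the full pipeline — data model, standardization,
stratified splitting, the seeded random search, pooling and selection,
cross-cohort evaluation with per-subtype metrics and ROC/AUC, a
from-scratch t-SNE for visual inspection — plus a synthetic two-cohort
generator so that every stage is testable without downloading cohort data.

## The selection procedure

Given a cohort and a signature of nominal length $L$:

1. **Standardize** every gene to zero mean and unit variance,
   $z = (x - \mu_g)/\sigma_g$, with $\mu_g$ the per-gene arithmetic mean
   and $\sigma_g$ the *population* (divisor-$N$) standard deviation. The
   divisor-$N$ form is used deliberately; at cohort sizes in the hundreds
   the difference from the $N-1$ form is far below measurement noise, and
   the population form is what the standard-scaler convention computes.
2. **Filter** the cohort to the signature genes (platform intersection may
   shrink the usable gene list; the *nominal* length is retained, see
   below).
3. **Split** into train/validation/test at 70/15/15, stratified by
   subtype.
4. **Search**: for every subset size $k$ in a band of the nominal length
   (default 10–80%, so $k \in \{\lceil 0.1L \rceil, \dots,
   \lfloor 0.8L \rfloor\}$ — 5..40 for a 50-gene signature), draw `trials`
   uniform random $k$-subsets, fit a linear-kernel SVM (C = 1) on the
   train part restricted to the subset, and score the subset by the
   **combined F1**: the arithmetic mean of macro-averaged F1 on the
   validation and the test part.
5. **Replicate** the search as several independent experiments (different
   seeds), pool all trials, and keep the best-scoring subset per size.
6. **Cross-evaluate** the winners on a second, independent cohort with a
   grid-searched SVM, reporting per-subtype one-vs-rest accuracy,
   precision, recall, F1 and AUC, confusion matrices, and a t-SNE view of
   the predicted test samples.

Because step 4 consumes both the validation *and* the test fold of cohort
1 (their mean is the selection criterion), cohort 1 provides no unbiased
performance estimate — by design. The unbiased assessment is step 6 on
cohort 2. This deliberate "leaky" selection is part of the procedure being
implemented and is why the cross-cohort stage exists at all.

### Design choices the procedure leaves open

Several details are not pinned down by the procedure's description; the
package fixes them as follows, each behind an explicit argument where
alternatives are plausible.

* **Combined score.** The combination of validation and test macro-F1 is
  the arithmetic mean (symmetric, keeps the score in $[0,1]$); `sum` and
  `min` combiners are available via the `combine` argument of
  `run_trial()` / `run_experiment()`.
* **Macro averaging.** Selection uses the unweighted mean of per-subtype
  F1, protecting the minority subtype (HER2-enriched) from being traded
  away for bulk accuracy.
* **One split per experiment.** All trials of an experiment share one
  split (drawn from the experiment seed), so that subset scores within an
  experiment are directly comparable; re-splitting per trial would
  confound subset quality with split luck. Replicate experiments use
  different seeds, hence different splits, and the pooled argmax is taken
  across all of them.
* **Stratified splitting** is the default: with four imbalanced subtypes,
  an unstratified 15% slice of a ~500-sample cohort can under-represent a
  subtype badly. `split_spec(stratified = FALSE)` restores simple random
  splitting. Part sizes follow largest-remainder rounding (70/15/15 of
  100 samples is exactly 70/15/15); within the stratified allocation each
  part's remaining seats go to the classes with the largest fractional
  remainders, ties broken by class order. Exact global part sizes are
  prioritized; per-class counts can sit one sample off the ideal where
  integrality forces it.
* **Nominal length.** A signature keeps its published length through
  platform intersection: a 50-gene signature of which 6 genes are
  unmeasured still searches sizes 5..40 (computed from 50), not 5..35.
  Subset sizes are only clipped to the available gene count at sampling
  time. This matches how the size band is quoted against the published
  signature even when fewer genes survive intersection.
* **Duplicate subsets are allowed.** Trials draw independently; at large
  trial counts and small $k$ the combination space is exhausted and
  deduplication would silently change the advertised trial count.
* **Per-trial seeds** derive deterministically from
  `(experiment_seed, k, trial_id)`, so any single trial is reproducible in
  isolation and a 10-trial run is an exact prefix of a 100-trial run.
* **Tie-breaking** in the per-size argmax: higher test-fold F1, then lower
  experiment id, then lower trial id — selection is invariant to the order
  in which experiments are pooled.
* **Cross-experiment equivalence.** The claim that replicate experiments
  agree is checked with a Kruskal–Wallis rank test on the per-trial
  combined scores at a given size (`compare_experiments()`); the protocol
  is flagged robust when $p > 0.05$. The test is nonparametric, handles
  more than two groups, and makes no normality assumption about F1
  distributions — the natural default given that the compared quantity is
  a bounded score. Note that with very large trial counts the test gains
  power to detect even the tiny systematic difference between experiments
  caused by their different splits; the robustness check is therefore
  meaningful at moderate trial counts (tens per experiment), where it is
  correctly calibrated (see the acceptance suite).

## The classifier

The selection phase uses a linear-kernel SVM with C = 1 — deliberately
simple, so that subsets are ranked by how *linearly* informative they are.
The evaluation phase wraps the same backend in a stratified
cross-validated grid search (`grid_search_train()`); the default grid is
the singleton {linear, C = 1, gamma = "scale"} and a wider grid is one
argument away (`classifier_spec(grid = list(C = c(0.1, 1, 10), kernel =
c("linear", "rbf")))`). The SVM itself is the e1071/libsvm implementation
— the package treats the large-margin optimizer as given and does not
re-derive it. Multiclass decision scores for ROC analysis are obtained by
summing each class's signed pairwise margins into a one-vs-rest style
score; AUC depends only on the ranking of scores, so any monotone
per-class score is equivalent for this purpose.

## Metrics

All evaluation metrics are computed from the multiclass confusion matrix:
per class, the one-vs-rest counts give accuracy $(TP+TN)/n$, precision
$TP/(TP+FP)$, recall $TP/(TP+FN)$ and F1 (harmonic mean). The "Acc"
column of the flat results table repeats the overall multiclass accuracy
(trace/$n$) on every subtype row — per-class one-vs-rest accuracy would
differ between rows, so a constant column can only be the overall value,
and that is what `format_metrics_table()` reports. Zero-denominator
precision or recall is reported as 0 with a warning (deterministic and
test-friendly). ROC curves sweep every distinct score threshold with tied
scores grouped; AUC is the trapezoidal integral and equals the
Mann–Whitney probability of ranking a random positive above a random
negative (ties counted ½) — an identity the test suite verifies against a
brute-force pair count.

## t-SNE

The 2-D embedding is implemented from its defining equations rather than
wrapped from a library, since the embedding is part of the method's
output. Input affinities use a Gaussian kernel with a per-point bandwidth
$\sigma_i$ calibrated by binary search so that the conditional
distribution's perplexity $2^H$ hits the target within $10^{-5}$;
conditionals are symmetrized, $p_{ij} = (p_{j|i} + p_{i|j})/2n$. (The
textbook one-line formula with a single global $\sigma$ and joint
normalization is inconsistent with per-point bandwidth calibration; the
package follows the standard per-point formulation and keeps the literal
global-$\sigma$ variant available via `global_sigma` for comparison.)
Output affinities are Student-t with one degree of freedom, jointly
normalized. Optimization is plain gradient descent on the KL divergence
with momentum 0.5 switching to 0.8 at iteration 250, learning rate 200,
early exaggeration ×4 for the first 100 iterations, Gaussian
initialization (sd $10^{-4}$), 1000 iterations — standard defaults, all
recorded in the result. Numerical guards: squared distances are clamped
at 0, $q$ is floored at $10^{-12}$ inside logarithms, and a non-finite
gradient aborts with the iteration index. The implementation is the exact
$O(n^2)$ algorithm; cohorts here are at most a couple of thousand
samples, for which no Barnes–Hut approximation is needed. The KL trace is
recorded every 10 iterations against the *un-exaggerated* affinities, so
its first and last entries are comparable.

## The synthetic generator

`synthetic_spec()` / `generate_cohort()` produce paired cohorts with
exactly the structure the method assumes, and nothing more:

* four subtypes with configurable (by default imbalanced) sample counts;
* a planted set of informative genes, each owned by one subtype
  round-robin and shifted by `effect_size` (default 1.6 against unit
  noise) in that subtype — all planted genes equally informative;
* all other panel genes pure Gaussian noise;
* per-cohort affine batch distortion (offset vector and scale factor),
  which per-cohort standardization removes exactly — mirroring why the
  standard scaler is the right normalization for this model;
* a configurable gene set withheld from cohort A, emulating signature
  genes missing from one platform (default: the six genes absent from the
  ACES platform, so cohort A has 44 of the 50 panel genes).

`make_study_shaped_pair()` fixes the shapes at 1512 × 44 and 515 × 50
with Basal well below LumA — a drop-in stand-in for the published data
layout. The default effect size was chosen once so that the full-panel
pipeline lands at macro-F1 ≈ 0.85–0.95: strong enough that informative
subsets separate from noise subsets, weak enough that tests remain
discriminative rather than saturated.

What the generator does **not** emulate: real microarray/RNA-seq
marginal distributions, gene–gene correlation (co-expression modules),
probe effects, label noise in subtype calls, or subtype structure beyond
mean shifts. Passing tests on generated data therefore demonstrate that
the machinery is correct and that the selection signal is recoverable
under the model's own assumptions — not that any particular subset size
suffices on real cohorts.

### What "recovery" means here

At desk scale the search runs 2 experiments × 2000 trials per size over
sizes 5..12 with 10 planted genes among 44. A uniform random size-10 draw
contains on average 2.3 planted genes, and the probability that any
single draw contains 9 or more of the 10 is below $10^{-5}$ per trial —
so *no* per-size best subset can be expected to contain 90% of the
planted set at this budget, regardless of how well selection ranks
subsets. Recovery is therefore defined as **coverage of the planted set
by the union of the per-size best subsets for sizes ≥ 10**: each winner
is heavily enriched for planted genes, and jointly the winners should
re-identify nearly all of them. This is the package's scaled-down
analogue of inspecting the gene lists that different selection runs
agree on.

## Problem sizes used by the tests and the acceptance script

The test suite and `scripts/acceptance.R` run the pipeline at reduced
scale, chosen once: the end-to-end check uses 2 experiments × 2000 trials
over sizes 5..12 on the 515-sample cohort (selection) and the 1512-sample
cohort (evaluation); the acceptance script uses 2 × 800 trials over sizes
8..12 plus 50 random reference subsets; the equivalence calibration uses
experiments of 25 trials, where the Kruskal–Wallis check is correctly
calibrated. t-SNE checks run on up to 200 points.

## Known limitations

* Uniform random search is the point of the method; no heuristic search
  (genetic algorithms, RFE, …) is provided.
* No multiplicity control is claimed over the max-statistic of millions
  of trials; the cross-cohort evaluation is the guard against selection
  overfitting.
* Gene matching is exact, case-sensitive symbol equality; no alias or
  identifier resolution.
* The loader rejects duplicate gene columns rather than guessing a
  collapse rule (collapse duplicates upstream if needed).
* Expression input is assumed continuous and already platform-processed;
  no quantile normalization or RMA is performed, and no batch correction
  beyond per-cohort standardization.
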