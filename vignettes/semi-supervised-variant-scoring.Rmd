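---
title: "Semi-supervised scoring of regulatory variants: model and design notes"
author: "pseudovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised scoring of regulatory variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudovar)
```

## The problem

Genome-wide association studies flag thousands of noncoding variants, but few
of them are functional: most tag a causal regulatory variant through linkage
rather than being one. Experimentally validated regulatory variants are
scarce, so a purely supervised classifier trained on them generalizes poorly.
`pseudovar` implements a self-training (pseudo-labeling) workflow around a
small 1-D convolutional network that scores variants by their per-variant
annotation profiles: a labeled set anchors the model, and a much larger
unlabeled variant pool is recruited through the model's own confident,
fold-consistent predictions.

The package consumes precomputed annotation matrices (variants x named
numeric features, e.g. chromatin-model outputs reduced to an immune-relevant
subset); it never computes sequence annotations itself.

## Dataset construction

Labels are built from association evidence, not from experiments:

* **Positives** — variants present in both of two collections (e.g.
  trait-associated GWAS variants that also carry a significant eQTL
  association), intersected on the coordinate key `chrom:pos:ref:alt`
  (`intersect_positive()`). Coordinates are used because rsID joins are
  ambiguous across annotation releases.
* **Negatives** — variants from the full association table with P-value
  strictly greater than 0.1 *and* allele frequency strictly greater than 0.3
  (`select_negatives()`): clearly null associations of common alleles.
  Boundary values are excluded because the rule is stated as strict
  inequality.
* The merged set is split 80/20 by an unstratified seeded shuffle
  (`split_dataset()`, half-up rounding of the test size); the 20% test set
  takes no part in any training step.

For experimentally curated evaluation sets the package also builds
matched negatives: pool variants within an inclusive ±1 kbp window of a
positive that are weakly conserved (conservation < 0.5) and common
(AF > 0.3) (`curated_negative_candidates()`), or positions sampled
uniformly from chromosome lengths at a minimum distance from every
positive (`random_genome_negatives()`).

## Feature selection

Two rankings over a wide annotation matrix are provided, both pure
functions of (matrix, labels, parameters, seed):

* `mutual_information_scores()` — per-feature mutual information with the
  label. Features with few distinct values use the plug-in estimator on the
  contingency table; continuous features use the nearest-neighbour
  estimator for a continuous variable against a discrete one (radius = the
  distance to the k-th same-class neighbour, k = 3 by default), after a
  `1e-10`-scale seeded jitter that breaks ties. Scores are clipped at 0.
* `rf_importance_scores()` — Gini impurity importance from a 500-tree
  random forest (`ranger`, `sqrt(p)` candidate features per split),
  normalized to sum to 1.

`select_top_k()` keeps the k best features (default workflow: k = 141,
matching the default network input length); ties are broken by ascending
original column index so selection is stable. How k should be chosen is
left to the user — the package treats it as a plain parameter.

## The classifier

`cnn_spec()` describes an eight-layer network: conv(kernel 5, 32 maps) →
max-pool(2) → conv(kernel 5, 64 maps) → max-pool(2) → flatten → dense(16)
→ dropout(0.1) → sigmoid(1). Convolutions are valid-mode (no padding,
stride 1) — with input length 141 the layer shapes are (137, 32),
(68, 32), (64, 64), (32, 64), 2048, 16, 1, which `trace_shapes()`
reproduces exactly. Pooling windows are non-overlapping and a trailing
remainder element is dropped (137 → 68).

Numerical choices:

* **GELU** uses the exact Gaussian-CDF form `x * pnorm(x)` (not the tanh
  approximation), in both convolutions and the dense layer.
* **Loss** is mean binary cross-entropy with probabilities clamped to
  `[1e-7, 1 - 1e-7]`, so a fully wrong prediction yields a large finite
  loss rather than infinity.
* **Optimizer** is minibatch Adam, learning rate 0.001, β₁ = 0.9,
  β₂ = 0.999, ε = 1e-8; 50 epochs and batch size 32 by default.
* **Initialization** is Glorot-uniform; initialization, epoch shuffling
  and dropout masks all draw from R's RNG, so `seed` makes training
  bitwise reproducible.
* **Dropout** is implemented as inverted dropout (mask ~ Bernoulli(0.9),
  surviving units scaled by 1/0.9) and applied only during training, so
  inference needs no rescaling and the score of a variant is a
  deterministic function of the fitted weights.
* The training loop lives in compiled code (RcppArmadillo) with
  convolutions batched as im2col matrix products; this is an
  implementation detail — the forward pass is pinned to a hand-computed
  oracle in the tests.

The functional-significance score of a variant is the trained network's
sigmoid output — the predicted probability of the positive (regulatory)
class. For hard calls, `choose_threshold()` maximizes Youden's J over
observed score cut points (rule: `score > threshold`), falling back to 0.5
when all scores are identical.

## The semi-supervised core

Given a labeled training set and an unlabeled pool
(`crossval_fold_predictions()`), the labeled set is partitioned into
k = 5 seeded folds; each fold's model (trained on the other four) scores
the whole pool, giving five out-of-fold probabilities per pool variant.
Two filters then decide which pool variants earn pseudo-labels:

1. **Consistency** (`ttest_consistency_filter()`): a two-sided one-sample
   Student's t-test of the five probabilities against 0.5. A variant is
   retained iff p < 0.05 — i.e. its five fold models agree it sits
   significantly away from the decision boundary. The published
   description of this test is ambiguous about the null; testing distance
   from the boundary is the reading under which retention means
   "confidently classified", and it is adopted here as a design decision.
   Zero-variance rows (all five probabilities identical) leave the t
   statistic undefined; they are retained iff their common value differs
   from 0.5, since perfect fold agreement is maximal consistency.
2. **Confidence** (`assign_pseudo_labels()`): the *mean* of the five
   probabilities is compared with a symmetric pair
   `(0.5 + delta, 0.5 - delta)`; above the upper cut → pseudo-positive,
   below the lower cut → pseudo-negative, inside the band → discarded.
   Aggregating by the mean is a design choice (the procedure is stated in
   terms of "the model-predicted probability" without an aggregation
   rule).

`threshold_grid_search()` tries delta ∈ {0, 0.1, 0.2, 0.3, 0.4}; for each
delta the retained pool is pseudo-labeled, merged with the labeled
training set at equal weight, and the model is retrained under fivefold
CV (`augment_and_retrain()`, which returns the fold model with the best
held-out-fold AUC). The delta whose retrained model scores the highest
AUC on the independent test set wins; ties go to the larger delta (fewer
but higher-confidence pseudo-labels). The widely useful end point is the
delta = 0.4 pair, i.e. the 0.9/0.1 rule. Pseudo-labeling runs for a
single round — no iterative self-training.

Counts are conserved at every stage: pool = t-test-retained +
t-test-discarded, and retained = pseudo-positive + pseudo-negative +
in-band discarded. Increasing delta can only shrink the labeled count.

`pseudovar()` wires all of this together and returns a classed fit with
`print`, `summary`, `predict`, `plot`, `coef`, `fitted` and `residuals`
methods; `compare_models()` and `classification_metrics()` produce the
seven-metric report (AUC, AUPRC, accuracy, precision, recall, F1,
specificity — with zero-denominator cells reported as 0 and flagged).
AUC is computed in the Mann–Whitney form (ties counted 1/2); AUPRC is
step-rule average precision, which avoids the optimism of trapezoidal
interpolation on PR curves.

## What the synthetic generator emulates — and what it does not

All tests run on synthetic data from `sim_config()` /
`simulate_annotation_dataset()` / `simulate_unlabeled_pool()` /
`simulate_eqtl_tables()` / `simulate_vcf()`. The generative model is
deliberately simple: class-conditional Gaussians in which a configurable
number of informative columns is mean-shifted by `effect` in positives
and centred at 0 in negatives, all columns sharing one noise SD. This
makes the Bayes-optimal AUC analytic (`pnorm(d / sqrt(2))` for
separation d), so oracle tests have closed-form targets, and the hidden
pool labels let pseudo-label precision be audited exactly.

What it does *not* emulate: correlation structure between chromatin
annotations, linkage disequilibrium between variants, class imbalance
drift, or heavy-tailed feature distributions. Passing tests therefore
demonstrate that the machinery is correct and that self-training recovers
planted signal under honest conditions — not that any particular AUC will
be achieved on real annotation matrices.

Default study conditions used by the acceptance workflow: 500 positives,
500 negatives, 141 features with 20 informative at effect 3 (noise SD 1),
an unlabeled pool of 2000 at prevalence 0.5. At these conditions the
classes are strongly (not perfectly) separable, which is the regime
self-training needs: confident pseudo-labels exist, and bad thresholds
are visibly punished on the test set. The heavy end-to-end runs train for
5 epochs rather than the default 50: the planted signal is separable
enough that the short schedule already meets the pseudo-label-precision
and AUC contracts those runs verify, and it is the package's chosen
problem size for routine verification.

## Known limitations

* The t-test reading of the consistency filter (one-sample against 0.5)
  is one of several defensible interpretations of the published
  procedure; the alternative (a dispersion test across folds) would
  retain a different set.
* Pseudo-labeling is one-shot; no self-paced or iterative refinement.
* No calibration of predicted probabilities; scores order variants well
  before they are honest probabilities.
* No confidence intervals on AUC/AUPRC (no DeLong or bootstrap).
* Genome-build handling is metadata only: no liftover, and no LD
  computation for sentinel/proxy reasoning.
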