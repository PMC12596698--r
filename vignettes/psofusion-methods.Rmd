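---
title: "psofusion: model, design choices and numerical details"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{psofusion: model, design choices and numerical details}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psofusion)
```

## The modeling problem

psofusion predicts labels for *pairs* of biological entities — two drugs, or
a drug and a disease — from heterogeneous per-entity binary feature
matrices. The central assumption is that an entity's *similarity profile*
(its row in the entity-by-entity Jaccard similarity matrix of one feature
type) is an informative, dimension-standardized representation: entities
that share targets, substructures or side effects behave alike, and a pair's
outcome is learnable from the two profiles. Every A-side feature type is
crossed with every B-side type; each of the resulting combinations gets a
dedicated network, so no single early-fusion step has to reconcile feature
types of wildly different dimension and sparsity.

The pipeline has three learned layers:

1. **per-combination networks** trained independently on concatenated
   profile pairs,
2. **swarm refinement**, which treats each network's flat weight vector as
   a particle position and moves all particles jointly using the canonical
   velocity/position update rules, re-training briefly after every move and
   scoring fitness as validation loss, and
3. **stacked integration**, a small network trained by ordinary
   backpropagation on the frozen base models' concatenated outputs.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| base `hidden_dims` | 512, 256, 128 | widths of the three hidden layers of every base network |
| stacker `hidden_dims` | 64, 32 | widths of the stacking network |
| `epochs` | 50 | preliminary training epochs per base model |
| `batch_size` | 128 | Adam mini-batch size |
| `learning_rate` | 1e-3 | Adam step size |
| inertia ω | 0.7 | weight on the previous velocity |
| cognitive c1 / social c2 | 1.5 / 1.5 | pull toward personal / global best |
| `iterations` | 10 | swarm iterations |
| `retrain_epochs` | 5 | gradient epochs after each particle move |
| `split` | 0.8 / 0.1 / 0.1 | train / validation / test fractions |

The first block of defaults reproduces the framework's reference settings;
an empty configuration override runs exactly those. `retrain_epochs` is not
fixed by the reference description beyond "re-training happens"; 5 epochs
keeps the refinement cheap relative to the 50-epoch preliminary phase while
still letting each particle adapt to its moved position.

## Design choices where the design was open

* **Representation.** Raw similarity rows are the default input; PCA
  (`representation = "pca"`, deterministic sign convention: each loading's
  largest-magnitude element is positive) is opt-in. Autoencoder reduction is
  deliberately not offered.
* **Jaccard of two empty supports is 0,** including the diagonal entry of an
  all-zero entity. An entity with no recorded features is not evidence of
  similarity to another featureless entity; scoring such pairs 1 would plant
  spurious structure exactly where data are absent.
* **Same-set pair ordering.** For DDI-style tasks the unordered pair
  (a_i, a_j) is presented once, lower entity index first. The full
  combination ensemble covers both feature-role assignments anyway; an
  `augment_symmetric` switch (off by default) additionally trains on both
  orderings.
* **Stochastic factors r1, r2** are drawn per *dimension* (standard swarm
  practice) even though they can be read as scalars; `r_mode = "scalar"`
  provides the one-draw-per-particle variant for fidelity experiments.
* **Velocities start at zero,** so the first move is driven purely by the
  best-difference terms. Since all particles start at their personal bests
  and one of them at the global best, the first iteration's moves are small
  and growth is controlled without a clamp; `velocity_clamp` is available
  for large parameter vectors.
* **Evaluated positions.** A particle's recorded position after a move is
  its *post-retraining* parameter vector: fitness is measured after
  re-training, so personal and global bests must refer to the parameters
  that were actually evaluated.
* **Stopping.** Fixed iteration count by default. With `convergence_tol`
  set, the swarm stops once the global-best improvement stays below the
  tolerance for 3 consecutive iterations.
* **Swarm semantics.** The swarm shares one global-best parameter vector
  across networks bound to *different* feature combinations. That is the
  literal reading of the refinement scheme and is implemented as such; the
  per-particle re-training step is what lets each network re-specialize to
  its own inputs after being pulled toward the global best. An alternative
  reading — optimizing only the models' integration weights — is noted as a
  possible extension and not implemented.
* **Stacker data.** The stacking network trains on the *training* split's
  base outputs. Training it on validation outputs would contaminate the
  fitness signal the swarm just used; an out-of-fold mode would cost one
  extra training round per fold and is left as future work.
* **Vote ties** break toward the lowest class index — deterministic and
  easy to reason about in tests.
* **Macro averaging** is the multiclass/multilabel default (micro and
  weighted are available). With no averaging mode stated for the reference
  results, comparisons against published multiclass tables would require
  the original datasets under both modes.
* **Binary decisions** threshold sigmoid scores at 0.5. The reported
  F-score is the harmonic mean of the *reported* (averaged) precision and
  recall.
* **Undefined metrics are NA.** Single-class truth makes AUROC/AUPRC
  undefined; they are reported as explicit `NA`, never silently defaulted.

## Numerical details

* Weights initialize uniformly on ±1/√fan_in, biases at zero, fully
  determined by the seed. Parameter vectors flatten layer by layer
  (input→output), weight matrix in column-major order, then the bias — the
  layout the swarm moves through.
* Softmax subtracts the row maximum before exponentiation; losses clamp
  probabilities at 1e-12 before taking logs. Non-finite training losses or
  fitness values raise an error naming the epoch (or particle and
  iteration) rather than propagating NaN.
* Adam uses β1 = 0.9, β2 = 0.999, ε = 1e-8 with bias correction; a zero
  learning rate provably leaves parameters untouched.
* AUROC is computed by pROC with a fixed orientation (higher score = more
  positive); AUPRC is average precision (mean of precision at each
  positive's rank). The test suite checks AUROC against an exhaustive
  concordance-pair oracle on all small inputs.
* Every seeded entry point restores the caller's RNG state, so nested
  seeded computations (retraining inside a swarm iteration) do not disturb
  the enclosing random stream; all pipeline seeds derive from one master
  seed via fixed substreams.

## The synthetic task generator

`synthetic_task_config()` emulates the statistical structure the framework
assumes, with no download: two entity sets (60 each by default) with three
sparse binary feature types per set, marginal density 0.15 over 40
indicator columns per type — sparse binary matrices of the kind produced by
target/substructure/side-effect annotations. Entities carry latent group
memberships (2 groups by default). For feature types in a designated
*informative pair*, indicator columns are group-biased (within-group
probability inflated by `group_bias = 0.8`, between-group deflated,
marginal density preserved), so within-group Jaccard similarity exceeds
between-group similarity — the generator plants signal exactly where the
method looks for it. Other types are i.i.d. Bernoulli and carry nothing.

Pair labels: for each informative type pair and each group, the product of
entity a's mean similarity to the group's A-side members and entity b's
mean similarity to its B-side members is summed over groups; the
standardized score enters a logistic link with slope `signal_strength = 10`
and each label flips with probability `label_noise = 0.05`. Because the
score has rank `n_groups` as a function of entity identity, models without
access to the informative similarity rows would have to infer per-entity
latent coordinates from the few labeled pairs each entity appears in
(500 sampled pairs by default), while the informative-pair model reads the
signal directly off its input. A design experiment during development
selected 2 groups: larger group counts make the planted bilinear score too
hard for the reduced networks to learn within the scaled-down training
budget.

What the generator does *not* emulate: real marginal statistics of curated
drug databases (heavy-tailed feature frequencies, cross-feature-type
correlations, annotation biases), multiclass adverse-event structure at
realistic class counts, or entity-disjoint evaluation splits. Passing the
planted-signal tests therefore demonstrates that the pipeline recovers
similarity-borne signal and that fusion does not destroy it — not that it
reproduces published benchmark figures on curated datasets.

## Problem sizes in the shipped tests

The test suite and the acceptance script run scaled-down configurations
chosen to exercise every code path at interactive speed: toy pipelines with
24 entities and 8/4-unit networks for smoke and determinism tests, and the
reference planted task (60+60 entities, 9 combinations, 32/16/8 networks,
10 training epochs, 5 swarm iterations, 500 pairs) for signal-recovery
checks across 5 seeds. The full suite completes in well under a minute on
one CPU.

## Known limitations

* Base models train sequentially; no parallel backend is wired in, though
  the per-combination structure is embarrassingly parallel.
* Similarity profiles grow quadratically with entity count; tens of
  thousands of entities would need blocked or sparse profile handling.
* Only pairwise entity interactions are modeled; higher-order combinations
  are out of scope.
* Regression tasks train and predict, but the six-metric report is defined
  for classification only.
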