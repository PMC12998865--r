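---
title: "Fusing frozen encoder embeddings: model, search and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing frozen encoder embeddings: model, search and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embedfuse)
```

## The problem

Large pre-trained image encoders ("foundation models") are routinely used
as frozen feature extractors in biomedical imaging: an encoder maps each
image to a dense embedding vector, and a lightweight classifier trained on
those frozen embeddings ("probing") measures how much task-relevant
information the embedding carries. Different encoders — histopathology,
radiology, vision-language — capture partly complementary and partly
redundant features, so combining several encoders' embeddings of the same
sample can outperform any single one. The practical questions are *which*
subset of a model pool to combine, *how* to combine them, and how to
evaluate the result, including under distribution shift.

`embedfuse` implements this workflow end to end, behind a provider
abstraction that makes the encoders pluggable: a provider is any function
from a dataset split to an embedding matrix. The shipped providers are a
synthetic multi-model generator and a trivial flatten-pixels baseline, so
the whole pipeline installs, runs and tests without downloading weights;
adapters for real encoders plug into the same one-function contract.

## Concatenation fusion

Given embeddings $e_i \in \mathbb{R}^{d_i}$ from $n$ models, the fused
representation is the feature-wise concatenation

$$e_{\text{concat}} = [\,e_1; e_2; \dots; e_n\,], \qquad
d_{\text{concat}} = \sum_{i=1}^{n} d_i .$$

Concatenation is parameter-free, keeps every model's features in an
isolated contiguous sub-block, and requires no fitting — `concat_fuse()`
is a pure function, and `fused_block()` recovers any input block
bit-for-bit from its column range. No cross-model normalisation is applied
by default: the downstream probe is a tree ensemble whose split decisions
depend on the ordering of feature values within a feature, not on absolute
scales, so heterogeneous block scales are harmless. A per-block z-scoring
flag (`zscore_blocks = TRUE`) exists for experimentation and defaults off.

The concatenation order is always the registry's insertion order and is
never permuted. Optimising the order would multiply the $2^n - 1$ subset
search by $n!$ orderings; a fixed order keeps the search tractable and the
results reproducible.

## The probe and the subset search

Embedding quality is scored by a gradient-boosted tree classifier
(XGBoost) trained on the frozen fused embeddings. During the search phase
every subset is scored with one *fixed* configuration — 250 trees,
learning rate 0.1, maximum depth 6, single-threaded with a fixed seed — so
that subset scores differ only through the embeddings. The objective
follows the task: binary logistic for two classes, the multi-class
probability objective otherwise, and an independent one-vs-rest binary
model per label for multi-label tasks.

`run_search()` enumerates every non-empty subset of the registered pool
($2^n - 1$ of them; 511 for a nine-model pool), fuses each subset's blocks
by concatenation, fits the fixed probe on the training split and records
validation *accuracy* — accuracy is the only selection metric; AUC is
reported at final evaluation but never drives selection. The winner is the
highest validation accuracy with deterministic tie-breaking: fewer models
first (a cheaper embedding generator at equal score), then earliest in
enumeration order. A `singles_only` mode restricts the search to the $n$
singletons; the best single model on validation is the "oracle single"
baseline. Failed subset evaluations are recorded with their reason and
skipped; the search aborts only if every subset fails.

`build_fusion_model()` packages the winning subset into a reusable
embedding generator: applied to any split it extracts the selected blocks
(through the cache) and fuses them with the same layout as during search.

## Final evaluation

For the selected subset, a bounded tuner searches nine boosting
hyperparameters (trees 50–1000, learning rate 0.01–0.3 log-uniform, depth
3–10, min child weight 1–10, subsample 0.5–1, column subsample 0.5–1,
gamma 0–5, L1 0–5, L2 0–5) for the configuration with the highest
validation accuracy. The sampler draws configurations independently and
uniformly (log-uniform where noted) and always evaluates the default
configuration as trial 0, so the tuned result can never fall below the
default. The sampler is a single internal function and can be replaced by
a model-based one without touching the surrounding machinery.

Test metrics (accuracy and AUC-ROC) are averaged over three probe seeds by
default (`n_final_runs = 3`), and the report carries the per-seed values.
Ordinal tasks are treated as multi-class.

## Self-attention fusion

As a trainable alternative to concatenation, each model's embedding is
linearly projected to a common width and treated as one token; a standard
scaled-dot-product multi-head self-attention block mixes the $n$ model
tokens; the fused vector is the mean over tokens. With head width
$d_{\text{head}} = 64$ and $n_{\text{heads}} \in \{4, 8, 12\}$ the output
width is $d_{\text{head}} \times n_{\text{heads}} \in \{256, 512, 768\}$;
the per-dataset width is chosen by fitting at each candidate and keeping
the best validation score.

The training recipe is a design choice of this package (the upstream
formulation leaves it open): a temporary linear softmax head is attached,
the whole block is trained end-to-end by cross-entropy with Adam
(default learning rate $10^{-3}$, batch size 32), early stopping on
validation accuracy with patience 10 epochs and at most 100 epochs, and
the head is discarded afterwards so the module remains an embedding
generator. Mean-pooling over tokens (rather than a class token or
flattening) keeps the output width equal to the projection width
regardless of the subset size. There are no residual connections or layer
normalisation — at these depths (one attention layer) they are
unnecessary, and their omission keeps the analytic gradients short.
Forward and backward passes are written directly in R and are verified in
the test suite against numerical differentiation and against an
independently coded brute-force attention computation. Non-finite training
loss raises an error reporting the epoch and learning rate. This strategy
supports single-label tasks only; multi-label training is rejected with an
error.

Self-attention fusion is the ablation variant, not the default: it
introduces parameters that must be learned from the task's training split,
which is exactly the over-fitting risk concatenation avoids.

## The synthetic data generator

The generator emulates a $K$-class dataset observed through $n$ virtual
encoders of differing informativeness. For model $m$ with dimensionality
$d_m$ and signal strength $s_m$, a sample with label $y$ gets

$$x_m = \mu_m[y] + w\, (z\, L_m) + \varepsilon, \qquad
\varepsilon \sim \mathcal{N}(0, \sigma^2 I),$$

where $\mu_m$ are per-class mean vectors, $z$ are shared latent factors
realised once per sample and projected through model-specific loadings
$L_m$ (weight $w$, the cross-model redundancy), and $\sigma$ is the noise
level. Labels belong to samples, not models, and all models see the same
sample order. Multi-label tasks replace the class mean by the sum of the
active labels' mean vectors.

Two calibration choices matter:

* **Planted strength is exact.** Raw class means are rescaled so the mean
  between-class squared distance is exactly $2 s_m^2 d_m$ (for
  multi-label, the mean squared mean-vector norm is $s_m^2 d_m$). Without
  this, the realised separation is a chi-distributed multiple of $s_m$
  varying by tens of percent across seeds, and "a model with signal 2" is
  not a well-defined experimental condition.
* **Noise default $\sigma = 3$.** At signal strength 2 and a few hundred
  training samples this puts a single informative block at roughly 85–90%
  probe accuracy: high enough to be clearly above chance, low enough that
  fusing two informative blocks gives a measurable gain instead of
  saturating at 100% (where the size-preferring tie-break would correctly,
  but uninformatively, pick a single model).

The corruption mechanism perturbs only the test split: each corruption
identity fixes a direction in embedding space, and severity $1\dots5$
scales both a mean shift along that direction and an inflation of the
noise, in units of the block's overall standard deviation. This preserves
the monotone severity structure the robustness metrics need.

What the generator does *not* emulate: real image statistics, the actual
modality structure of encoder pools, label noise, class imbalance, or the
specific artefacts of image-space corruption benchmarks (stain shifts,
motion blur, ...). Passing tests therefore demonstrate that the selection,
fusion, caching and evaluation machinery behaves correctly under planted,
controllable conditions — not that any particular encoder pool will
transfer to any particular clinical task.

## Metrics

* **Accuracy** is correct over total; for multi-label tasks it is the
  per-label binary accuracy averaged over labels (the convention
  consistent with multi-label benchmark reporting, where exact-match
  accuracy would be far lower than the values reported alongside AUC).
* **AUC-ROC** is the probability that a random positive outscores a random
  negative, ties counting one half; computed by the rank (Mann–Whitney)
  construction. Multi-class AUC is the macro one-vs-rest average (the
  MedMNIST-style convention); multi-label is the macro per-label average.
  Single-class inputs raise an error rather than silently returning 0.5.
* **Balanced error** is one minus the mean per-class recall.
* **Robustness (BE, rBE).** Against a reference model's error table over
  (corruption, severity) conditions — 11 × 5 = 55 in the standard
  benchmark — each corruption contributes the ratio of severity-summed
  balanced errors; BE is the mean ratio over corruptions (reference = 1).
  rBE applies the same construction to the *increase* of error over the
  clean test set, and is legitimately negative when the candidate degrades
  less than its clean error while the reference degrades more. The default
  aggregation (ratio of severity sums, then mean over corruptions) follows
  the ImageNet-C-family convention; a literal per-condition-ratio mean is
  available as `mode = "pair_mean"` because the phrase "averaged over all
  55 pairs" is ambiguous. Raw ratios are the default scale; `scale_100`
  multiplies by 100 for the convention where the reference is 100.

## The cache

Embedding extraction is the expensive step in practice, while the search
is exponential in the pool size, so blocks are cached on disk keyed by
(model, dataset, split) plus a content tag. The layout is one NPY array
(the field-standard array container, language-portable) plus a JSON
manifest carrying sample ids, labels, dims and the key fields, making a
cache directory self-describing. The content tag is the first 12 hex
digits of an MD5 digest (base R's built-in hasher) over the provider-pool
version and a dataset fingerprint, so a changed provider silently misses
rather than silently reusing stale blocks. Loading validates the manifest
against the array and raises an integrity error on mismatch — a corrupted
entry is never reported as merely absent. With the cache on, each provider
is invoked at most once per (model, split) for an entire search: 27
extractions against 511 subset evaluations for a nine-model pool.

## Numerical and degenerate-input choices

* Probes run single-threaded with a fixed seed; all randomised components
  (generator, tuner, attention training, run averaging) are reproducible
  from their seed.
* Accuracy ties in the search break toward smaller subsets, then
  enumeration order; tuner ties break toward the earliest trial (hence the
  default configuration).
* Degenerate inputs fail loudly: empty block lists, misaligned sample ids
  (first mismatching id named), single-class training labels, severity
  outside 1–5, zero reference denominators in robustness tables,
  truncated cache arrays.
* Attention training with zero epochs is permitted (useful for analytic
  checks) and returns the initialised block.

## Problem sizes

The shipped experiments are desk-scale by design: unit tests use 150–600
training samples and 4–8-dimensional blocks; the planted-recovery
experiment uses five 8-dimensional models with 500/200/200 splits over ten
seeds; cache-economics uses nine 4-dimensional models (511 subset
evaluations). These sizes keep the full test suite under two minutes on a
single CPU while exercising every code path at the probe's real
configuration (250 trees).

## Known limitations

* No adapters to real pre-trained encoders are shipped (the provider
  contract is the extension point); consequently no claims are made about
  real benchmark performance.
* Self-attention fusion is single-label only and trains in plain R — fine
  at desk scale, not intended for thousands of samples at width 768.
* The tuner's sampler is uniform random; a model-based sampler would reach
  good configurations in fewer trials on large spaces.
* The cache has no eviction or concurrency story; it is a build artifact
  directory, not a database.
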