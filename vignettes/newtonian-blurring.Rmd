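---
title: "Newtonian blurring: methods, model and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Newtonian blurring: methods, model and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(newtblur)
```

## The procedure

A subject's connectome is reconstructed by probabilistic tractography,
so repeating the pipeline R times yields R weighted graphs over the same
ROI parcellation that agree on most, but not all, edges and weights.
`newtblur` implements two consensus/augmentation schemes over such a run
ensemble:

**Basic averaging** (`basic_average()`): an edge survives only if its
fiber count is nonzero in all R runs; its weight becomes the arithmetic
mean of its R weights after deleting one minimum and one maximum
occurrence. One consensus graph per subject.

**Newtonian blurring** (`newtonian_blur()`): the same
zero-filter/trim/average recipe is applied to every k-element subset of
the runs, each subset yielding one graph. The name refers to the
binomial coefficients that govern the construction: C(R, k) graphs per
subject, and an edge with zero weight in exactly z runs survives in
C(R − z, k) of them (`edge_survival_count()`). Basic averaging is the
degenerate configuration k = R.

Both schemes only ever *select and average observed weights*; no noise
is injected. That is the augmentation's defining property: the augmented
graphs are as "real" as the consensus graph, just less strongly
error-corrected (5 weights averaged instead of 8 at the defaults), which
is what makes the set diverse enough to be useful for training.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `R` | 10 | tractography repetitions per subject |
| `k` | 7 | runs per subset; C(10, 7) = 120 graphs per subject |
| `trim` | 1 | weight occurrences deleted per extreme before averaging |

The defaults reproduce the production configuration of the public
120-fold augmented connectome dataset; `aug_config()` accepts any
(R, k, trim) with k ≤ R and k − 2·trim ≥ 1.

## Numerical and tie-break conventions

- **Trimming under ties.** "Delete the maximum and minimum" removes
  exactly one occurrence per extreme per trim step: an all-equal list of
  seven weights still loses two entries and averages the remaining five.
  Any other convention would make the trimmed mean discontinuous in the
  weights.
- **Subset order.** Subsets are enumerated in lexicographic order over
  run indices (1-based, the R convention). The order is the naming
  contract: `augmented_name()` assigns the 0-based file suffixes
  `s000..s119` in that order, so reruns are byte-identical.
- **Zero-filter scope.** The zero filter looks only at the k chosen
  runs; an edge absent solely from unchosen runs survives that subset.
  This is what produces the C(R − z, k) survival law.
- **Floating point.** Weights are doubles (trimmed means are
  fractional); the trimmed mean sums in ascending order for a
  deterministic result. The matrix fast path used by the blur
  (sum − max − min for trim = 1) agrees with the per-vector definition
  to ~1e−13 relative, which the tests assert.
- **Degenerate inputs.** An empty graph is valid everywhere; the Jaccard
  distance of two empty edge sets is defined as 0 (self-distance of the
  empty graph) and flagged with a message.
- **Edge keys.** Undirected edges are stored canonically as
  (min, max); absence encodes weight 0, so no zero-weight edge is ever
  stored. Zero-weight rows in input files are dropped with a warning
  rather than rejected, since upstream pipelines occasionally emit them.

## The Jaccard diagnostics

`jaccard_distance()` uses unweighted edge sets —
|symmetric difference| / |union| — because the question it answers is
whether augmentation changes *which* connections are present, not their
strengths. It is a metric (tested: symmetry, identity, bounds, triangle
inequality). `pairwise_class_distances()` computes all within-A,
within-B and across distances of two graph sets via a 0/1
edge-incidence matrix and one cross-product, so the 28,680 pairs of two
120-graph sets cost one small matrix multiplication.
`distance_histogram()` uses left-closed right-open bins anchored at 0
with default width 0.005, narrow enough to resolve the within-subject
peak near zero.

## The synthetic cohort generator

Real repeated-tractography data cannot ship with the package, so
`generate_cohort()` draws cohorts with the statistical structure the
method operates on:

1. a population **backbone** of candidate node pairs
   (`backbone_density`, default 0.3 of all pairs), fixed by the master
   seed; a fixed 10% of it is the designated class-signal subset;
2. a per-subject **latent graph**: each backbone edge is included with
   `subject_edge_prob` (default 0.5; + `class_effect`, default 0.1, on
   the signal subset for class +1 subjects), and carries a log-normal
   latent mean fiber count (`mean_fibers` = 30, log-sd
   `fiber_dispersion` = 0.8) — the simplest skewed count model;
3. per-run **detection noise**: each latent edge appears in a run with
   `detection_prob`, with a zero-truncated Poisson fiber count around
   its latent mean (`run_weight_noise = "none"` gives the noiseless
   limit for testing).

All randomness derives from the master seed through per-subject
substreams keyed by subject index, so individual subjects are stable no
matter how many are generated, and equal configs give identical cohorts.

**Calibration of `detection_prob`.** The default 0.99 was chosen
analytically, before running the pipeline, to place the within-subject
augmented Jaccard distances in the few-percent regime observed on real
repeated tractography: with per-run miss probability q, a latent edge
has z = 1 zero runs with probability 10·q·(1−q)⁹ and then appears in 36
of the 120 graphs, so the expected within-subject distance is roughly
(10q·0.42)/(coverage) ≈ 0.04 at q = 0.01, versus ≈ 0.12 at q = 0.03,
which would already be larger than typical *between*-subject distances
on very similar real subjects. With the defaults, simulated
within-subject means come out near 0.04 and between-subject means near
0.7 — the generator reproduces the *ordering* and the within-subject
scale, not the between-subject value of any particular real pair, since
that depends on cohort-specific anatomy.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: spatial/anatomical edge structure (hubs,
distance-dependent connection probabilities, hemispheric symmetry), the
joint five-resolution hierarchy (each resolution is generated
independently), realistic between-subject similarity (real subjects
share most of their backbone; synthetic subjects share only the
candidate set, which makes between-subject distances larger than real
ones), and any weight–distance or weight–degree correlations.

## The SVM experiment

Features are binary edge indicators: the upper triangle of the
adjacency matrix flattened in lexicographic pair order
(`graph_to_features()`, length n(n−1)/2). The classifier is the linear
soft-margin SVM, and the augmentation interacts with its objective
through the penalty: replacing each training point by `fold` copies
multiplies the slack sum by `fold`, so `scale_penalty()` divides C by
the fold (C/120 at the defaults). With *exact* copies this provably
preserves the optimum, which the tests verify to 1e−6.

`augmentation_experiment()` splits **subjects**, never graphs — no
augmented graph of a test subject can reach training, and the code
asserts it. The split is stratified by label at fraction 0.7 (which
reproduces the 737/316 shape on a 1053-subject cohort). The plain arm
trains on one basic-average graph per training subject — the natural
non-augmented baseline, since basic averaging is the established
consensus construction; the augmented arm trains on all 120 blurred
graphs per training subject at C/120. Both are evaluated on the same
basic-average test graphs. Train accuracy of each arm is measured on
that arm's own training set. The default grid is log10 C ∈ [−4, 2] in
steps of 0.5.

**Two solvers.** `train_linear_svm()` wraps libsvm (e1071) and solves
the exact objective with an unregularized intercept; it is the
reference implementation used in the contract, duplication and
grid-oracle tests. `dcd_linear_svm()` implements dual coordinate
descent with shrinking (the LIBLINEAR algorithm) in C++; it carries the
intercept as an appended constant feature (so the bias is weakly
regularized, as in LIBLINEAR and scikit-learn's `LinearSVC`) and
supports per-instance costs, which lets exactly duplicated augmented
rows collapse into multiplicities without changing the optimum (hinge
slacks of identical points add). On the fold-expanded training sets of
the experiment the two produce indistinguishable accuracies, but the
coordinate-descent path is roughly sixty-fold faster, so the experiment
defaults to it. Tests pin both: the libsvm path against a
brute-force objective grid, the dcd path against its own
(bias-regularized) objective, and the two against each other.

**Problem sizes.** The shipped experiments run at a desk scale chosen to
exercise every code path while keeping the suite quick: cohorts of 120
subjects at 40 nodes with 5 independent seeds for the
augmented-vs-plain comparison (84 training subjects → 10,080 augmented
training graphs per cohort), two 83-node subjects for the deviation
analysis, and 1053-subject cohorts at small node counts for the
dataset-scale counting checks.

**What the experiment shows at this scale — and what it does not.**
Across replicate synthetic cohorts the difference between the augmented
and the plain arm's mean test accuracy on the upper half of the C grid
is statistically indistinguishable from zero (a 20-cohort estimate puts
it at −0.003 ± 0.009): under this generator, augmentation neither helps
nor hurts. The mechanism is visible in the calibration: at
`detection_prob` = 0.99 the 120 blurred graphs of a subject are nearly
identical to its basic-average consensus graph, so the augmented arm at
C/120 approaches exact 120-fold duplication — which provably reproduces
the plain solution. The consensus baseline already contains essentially
all the information the blurred copies carry. A positive augmentation
benefit on real cohorts therefore has to come from structure this
generator deliberately does not model (anatomically correlated edge
flicker, a weaker or noisier non-augmented baseline, far larger feature
spaces); a test of the ordering on synthetic data probes the
experimental machinery, not the real-data effect size. The absolute
accuracies are likewise properties of the synthetic signal strength
(`class_effect` = 0.1, a deliberately weak signal), not of any real
cohort.

## Known limitations

- The generator's between-subject distances are larger than those of
  real, anatomically similar subjects; only the within/between ordering
  and the within-subject scale are meaningful.
- Distances compare edge sets only; a weighted-graph distance is out of
  scope.
- The three distance classes visibly form unimodal, roughly Gaussian
  histograms, but no distribution fitting is provided.
- A logistic-regression variant of the experiment would show the same
  penalty-rescaling structure but is not implemented.
- Choosing R = 10 (or k, trim) adaptively from data is out of scope;
  the defaults are taken as given.
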