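---
title: "Bayesian network feature selection for TOF-MS peak tables: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian network feature selection for TOF-MS peak tables: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Profiling studies with time-of-flight mass spectrometry (TOF-MS) produce a
peak-intensity table: a few hundred cases (spectra of blood serum or other
samples, often several replicate spectra per patient) by up to a few hundred
features, each feature the fitted abundance of a peak at one m/z position.
The analytical goal is to find the peaks whose abundance depends on the
disease class, and to do so *stably*: with so few cases relative to
features, classifier-wrapper selection methods happily assemble feature
sets that change wholesale between cross-validation randomizations and
collapse on withheld data. A second, subtler goal is to recover the
*relationships among peaks* — protein modifications, doubly charged ions,
and convolution of adjacent peaks all produce features that are strongly
correlated with a "parent" peak and carry no independent diagnostic
information, yet are exactly what a biochemist needs to see to identify
the underlying molecule.

`bnpeaks` addresses both goals with a class-rooted Bayesian network built
from model-free mutual-information (MI) tests, assessed under repeated
stratified cross-validation.

## The method

### Discretization

Each feature is reduced to three levels — low, medium, high — by a
boundary pair $(b_{low}, b_{high})$ chosen to maximize
$MI(\text{class};\, \text{binned feature})$, computed with empirical
frequencies in log base 2 (bits). The three-bin form isolates the central
abundance range, where the class-conditional distributions overlap and
carry little discrimination, from the two tails where they differ. A value
exactly on a boundary falls in the middle bin, keeping the outer bins
strictly extreme.

When a feature has at most 64 distinct values the search is exhaustive
over all midpoints between consecutive sorted distinct values. Above that,
a two-stage search is used: a coarse sweep over the midpoints of 64 evenly
spaced sample quantiles, then an exhaustive local search over the
distinct-value midpoints within one coarse step of the coarse optimum.
The refinement keeps the quantile mode within 0.01 bits of the exhaustive
reference (measured worst case 0.008 bits over random features with 200
distinct values) at a small, bounded cost; both stage sizes are
parameters of `bn_settings()`. Features with fewer than three distinct
values fall back to a flagged two-level or constant binning.

### The significance threshold

The selection threshold is calibrated by permutation. The table is
discretized once against the true labels; class labels are then shuffled
`n_perm` times (default 100) and $MI(\text{shuffled class};\,
\text{binned feature})$ is evaluated on that fixed discretization. The
largest value over all features and permutations is the *baseline*; the
working threshold is `multiplier` times the baseline, default 3.2.

The multiplier is essential and deliberately large: the per-feature MI
values being screened were each *maximized* over boundary pairs, so they
are biased upward relative to the fixed-bin permutation null. Using the
raw baseline as the threshold admits far too many features. The default
3.2 was chosen empirically in the originating study (feature-set sizes
fall monotonically with the multiplier while the cross-validated error
has a flat minimum); `sweep_multiplier()` reproduces exactly that
diagnostic, and `permutation_baseline(rediscretize = TRUE)` offers the
alternative null in which every permutation re-optimizes the boundaries,
which absorbs the maximization bias into the baseline itself and is the
appropriate comparison when asking whether a *single, already maximized*
MI value is distinguishable from chance.

The baseline is computed once on the full table before cross-validation
and shared across folds (`recompute_threshold = FALSE`), trading a small
optimistic bias in the threshold — not in the boundaries, which are
always refit per fold — for comparability of arc tallies across folds; a
flag recomputes it per training fold.

### Building the network

The class node is fixed as the root: diagnosis is treated as causal to
abundance changes, never the reverse, which reduces intractable structure
learning to two passes of pairwise tests.

1. *First level.* Every feature whose maximized MI with the class
   strictly exceeds the threshold receives an arc from the class node.
2. *Feature-feature links.* Each first-level feature is tested against
   every other feature on the already-binned values. Because a 3x3 pair
   can reach $\log_2 3$ bits while a binary class pair is capped at 1
   bit, the comparison is scale-adjusted: a link is placed when
   $MI / \log_2(\min \text{alphabet})$ exceeds
   $\text{threshold} / \log_2(\#\text{classes})$.
3. *Serial-chain pruning.* For a linked pair of first-level features
   $(V_1, V_2)$, the conditional MI $MI(C; V_2 \mid V_1)$ is compared
   with $MI(C; V_2)$. A fractional drop strictly greater than
   `drop_threshold` (default 0.75) indicates the chain
   $C \to V_1 \to V_2$: the class arc to $V_2$ is removed and $V_2$
   becomes a child of $V_1$. If both directions drop — common when both
   features descend from one cause — the parent is the feature retaining
   the greater conditional MI with the class, the same quantity that
   directs arcs between pairs where neither direction drops. The
   threshold is strict ("exactly 75%" is not a demotion) and
   configurable; chains of multiply charged states organize correctly
   over a wide range but start to be missed above about 0.9.
4. *Children.* A link from a first-level feature to a non-first-level
   feature is directed immediately (the causality assumption again). By
   default such a child attaches only to its single strongest first-level
   parent by MI; `multi_parent = TRUE` keeps all such arcs. Grandchildren
   ("third level") are not searched.

Pairs are processed in descending order of the stronger member's class
MI, and any orientation that would close a directed cycle is skipped and
logged, so the result is always a DAG with the class as sole root. Every
decision (class link, demotion with its drop fraction, direction choice,
skip) is returned as an auditable log.

The surviving first-level features form a Markov blanket of the class
node: conditioned on them, every other feature is (approximately)
independent of the class, so they alone feed the classifier.

### Stability under repeated cross-validation

`run_cv()` repeats stratified k-fold cross-validation (defaults k = 10,
100 repeats), re-randomizing fold membership each repeat; stratified
dealing keeps each fold's class proportions within one case of the
population's, and an optional case-group column keeps replicate spectra
of one patient in a single fold. Within each fold the discretization,
threshold comparison, network construction and parameter fitting see
training cases only; the held-out fold is binned with the frozen training
boundaries (out-of-range values bin as low/high like any others). Across
n repeats this records n x k networks and n per-repeat error rates. Arc
frequencies over the recorded networks measure selection stability, and
`build_consensus()` keeps arcs appearing in more than `freq_threshold`
(default 0.5) of networks, resolving direction by majority and skipping
arcs that would orphan or cycle the DAG.

The final classifier is refit on the full table: boundaries re-optimized
on all cases, class prior and per-feature conditional probability tables
(3 x #classes, Laplace pseudocount 1 by default) estimated empirically,
and everything frozen into a serializable object. Posteriors are
accumulated in log space, calls use a strict 0.5 threshold on the
positive-class posterior (a posterior exactly at the threshold is a
negative call), and ROC curves sweep the threshold over [0, 1].

## The synthetic model

`synthetic_spec()` emulates the structure of a processed TOF-MS peak
table with known ground truth; it exists so that structure recovery can
be measured against a designed answer.

* **Primaries.** Five features whose class-conditional Gaussian means are
  1-2 SD apart (defaults 1.0, 1.25, 1.5, 1.75, 2.0 SD, alternating
  direction), the separation range reported for real serum profiling
  data. Per-feature baseline means are uniform on 20-100 intensity units
  with coefficients of variation of 0.15-0.35, loosely matching fitted
  peak-amplitude tables.
* **Children.** Seven features each carry a random but bounded fraction
  (uniform per case on [0.5, 1]) of a primary, plus independent Gaussian
  noise at 0.3 of the parent SD — the signature of protein modifications
  and related systematic effects. One child is a doubly charged ion and
  sits at exactly half its parent's m/z.
* **Convolution.** A fixed 30% of one primary's signal is moved, case by
  case, into a neighboring otherwise-noise peak, replicating the overlap
  of adjacent peak shapes.
* **Hidden-parent fragments.** Two features are children of an
  *unobserved* class-dependent variable (a large protein outside the
  measured mass range). The first fragment is coupled tightly (transfer
  uniform on [0.75, 0.95], noise 0.15 of the latent SD), the second more
  loosely ([0.35, 0.65]); the expected recovery is therefore one fragment
  at the first level with the other as its child — the method cannot see
  the latent parent, and a consistent asymmetry between the fragments
  keeps the recovered surrogate stable across folds. With symmetric
  fragments the direction of the recovered pair flips between folds and
  no consensus forms; the asymmetry is part of the designed ground truth.
* **Noise.** All remaining features are drawn from a single
  class-independent Gaussian each.

Intensities are truncated at zero after all mixing. The per-feature
distribution parameters are drawn from the spec's own seed, separately
from the case-level noise, so independent draws (training vs lockbox in
`make_lockbox()`) come from one generative model.

What the generator does *not* emulate: raw spectra (no peak shapes,
baselines, alignment error, or amplitude drift — the pipeline starts at
the peak table), heavy-tailed or multimodal abundance distributions,
batch effects, and correlated noise across noise features. Passing
structure-recovery tests on this model therefore shows that the
algorithm recovers the designed dependency structure under Gaussian
class-conditional variation at realistic separations, not that it is
robust to every artifact of real spectra.

## Numerical and design choices

* Probabilities inside MI and conditional MI are plain empirical
  frequencies; $0 \log 0 = 0$. No bias corrections (Miller-Madow or
  otherwise) and no continuous MI estimators: the model-free, discrete
  formulation is the method.
* Smoothing exists only in the classifier (Laplace pseudocount, default
  1, exposed).
* Class labels are coded in first-seen order; reports show original
  strings. The second class level is the default "positive" class for
  posteriors and ROC curves.
* Ties in the boundary search resolve to the first pair in a fixed
  deterministic order; identical seeds and settings reproduce every
  result bit for bit, including each repeat's fold assignment
  (`seed + repeat` substreams).
* Replicate spectra are independent cases by default; a group column
  confines them to common folds without entering the model otherwise.
* Degenerate situations are first-class: empty first level (warned,
  majority-class fallback in CV), constant features (middle bin, zero
  MI), missing cells (rejected with coordinates, or dropped by flag).

## Problem sizes used by the shipped checks

The packaged tests run the full protocol on the default synthetic model
(400 cases x 96 features) with 25 cross-validation repeats — 250
recorded networks — which estimates arc frequencies to within a few
percent and completes quickly; the acceptance script
(`scripts/acceptance.R`) runs the full 100 repeats (1000 networks). The
lockbox-consistency check uses 20 generator seeds with a 200-case
training table and a deliberately large 400-case lockbox: the quantity
under test is the *difference* between the lockbox error and the
CV-predicted mean, so the lockbox is sized to make its own sampling
noise small, and the comparison scale combines the CV repeat-SD with the
binomial SD of the lockbox estimate — both sources of variance are real,
and omitting the second would make the check fail occasionally even for
a perfectly calibrated predictor.

## Known limitations

* The empirical multiplier (3.2) is a calibrated constant, not a derived
  quantity; `sweep_multiplier()` is provided precisely because a new
  data set may sit elsewhere on the stability/error trade-off.
* Hidden variables are not modeled: a latent parent appears as one
  surrogate first-level feature plus children, and only a consistent
  asymmetry among its observed children makes the surrogate stable.
* Child features linked to two first-level features keep one parent by
  default; the original procedure's behavior in that case is not
  documented, and `multi_parent` exists for the alternative.
* With more than two classes the classifier falls back to
  maximum-posterior calls and the ROC utility still requires a
  designated positive class.
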