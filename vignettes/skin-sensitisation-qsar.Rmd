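---
title: "Classifying skin sensitisers from topological descriptors: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying skin sensitisers from topological descriptors: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinqsar)
```

## The problem

A skin sensitiser is a substance that induces an allergic response after
skin contact. The murine local lymph node assay (LLNA) quantifies potency
as EC3, the concentration eliciting a three-fold stimulation index; by
convention EC3 < 0.1% is an Extreme sensitiser, 0.1–1% Strong, 1–10%
Moderate, above 10% Weak, with non-classified (NC) compounds treated as
non-sensitisers. Regulatory screening wants a structure-only predictor of
the binary sensitiser / non-sensitiser outcome, so that animal tests can
be reserved for borderline cases.

`skinqsar` implements that workflow end to end: molecular graphs from
SMILES, a panel of fourteen topological/compositional descriptors, min–max
normalization, two descriptor-selection routes, two classifiers — an
Adaptive Fuzzy Partition (AFP) rule model and a one-hidden-layer
perceptron (MLP) — a min–max applicability domain, and the usual
confusion-matrix statistics. Because the curated 209-compound LLNA dataset
is not redistributable, the package also ships a synthetic descriptor
generator that reproduces the *shape* of that study (class imbalance,
descriptor ranges, correlated nuisance descriptors) so every stage is
testable.

## Descriptor panel

All descriptors are computed on the hydrogen-suppressed molecular graph;
hydrogen counts enter only the two composition measures. With `A` heavy
atoms and vertex degrees $\delta_i$:

* `NN`, `O-058`, `nCconj` — counts: nitrogens; `=O` fragments (oxygen
  double-bonded to a heavy atom); non-aromatic sp² carbons whose double
  bond is conjugated, through one single bond, with another multiple or
  aromatic bond.
* `GNar` $= (\prod_i \delta_i)^{1/A}$, the Narumi geometric index.
* `PW2`, `PW3` $= \frac1A \sum_i p_i(k)/w_i(k)$, the Randić shape indices
  (atomic simple-path over walk counts, length `k`).
* `IVDE` — Shannon entropy (base 2) of the vertex-degree classes.
* `X2v`, `X3Av` — Kier–Hall valence connectivity: over simple paths of
  `k` bonds, $\sum (\prod \delta^v_i)^{-1/2}$ with
  $\delta^v = (Z^v - h)/(Z - Z^v - 1)$; `X3Av` divides by the path count.
* `GGI8` — Galvez charge index: with adjacency `M` and
  $Q_{ij} = d_{ij}^{-2}$, `CT = MQ`, summing $|CT_{ij} - CT_{ji}|$ over
  pairs at topological distance 8.
* `EEig10r` — 10th-largest eigenvalue of the edge adjacency matrix with
  resonance-integral bond weights (single 1, aromatic 1.5, double 2,
  triple 3) on the **diagonal** and unit entries between incident edges.
  Line-graph spectra are bounded below by −2, which pins the index at
  ≥ −1 for saturated skeletons — exactly the published training minimum —
  whereas putting the weights off-diagonal would push routine molecules
  to −2 and below, outside the published domain. That observation fixed
  the convention here.
* `PCR` — ratio of the weighted to the plain simple-path count over paths
  of length 1..A−1, each path weighted by the *geometric mean* of its
  conventional bond orders (aromatic 1.5). The geometric mean keeps
  saturated skeletons at exactly 1.0 and bounds the ratio by the mean
  bond order, matching the published 1.0–1.7 domain; a raw product would
  score benzene alone near 4.
* `Me`, `AAC` — mean carbon-scaled Sanderson electronegativity and the
  element-composition entropy, both over all atoms including implicit
  hydrogens. The Sanderson table ships with the package
  (`sanderson_electronegativity()`); unknown elements are an error, not a
  silent default.

Single-atom fragments return 0 for all topology indices so batch
computation can proceed; multi-fragment SMILES (salts) are reduced to the
largest fragment with a warning, because every index here is a
whole-graph quantity.

The SMILES dialect covers the organic subset, bracket atoms with charge
and explicit hydrogen counts, branches, and ring closures; aromaticity is
taken from lowercase notation, plus perception of six-membered C/N rings
written in alternating Kekulé form. Stereochemistry is parsed but not
retained — no descriptor in the panel is stereochemical.

## Adaptive Fuzzy Partition

The AFP classifier recursively splits the (normalized) descriptor space
into fuzzy subspaces. A candidate cut on axis `a` at position `t` turns an
interval into two trapezoidal fuzzy sets whose geometry follows two fixed
ratios: support width 1.25·w and core width 0.45·w, both centred on the
interval of width `w`. Membership is 1 on the core, 0 outside the
support, linear between. Two conventions complete the construction:

* **Boundary saturation.** A side of an interval that was never created
  by a cut (the outer border of the axis) is a half-trapezoid saturated
  at 1 outward. Without this, the most extreme training compounds on
  every axis would sit on the shoulder below the 0.5 threshold and be
  unpredictable by construction. Out-of-range behaviour on saturated
  sides is instead policed by the explicit min–max applicability domain.
* **Rules constrain only cut axes**, so the root model is a single
  universal rule and each rule holds at most one trapezoid per axis.

Cut candidates are the midpoints between consecutive sorted unique member
values (finite, deterministic, scale-free). Candidate splits are ranked
by a local separation score — the absolute difference in
membership-weighted class shares between the two children, memberships
raised to the weighting coefficient 1.5 — and the best-ranked split is
**accepted only if the global training classification score** (fraction
of compounds attributed to their own class, abstentions counting as
misses) **improves by at least the tolerance, 0.001**. The local score
alone will happily isolate two mislabelled compounds (score ≈ 1
regardless of how few points are involved), shredding the partition; the
global-gain gate rejects exactly those splits because they push
correctly-classified neighbours below the membership threshold. Training
also stops when a child would hold fewer than 2 compounds, an axis
reaches 5 cuts, a class reaches 30 rules, or after 30 iterations — the
published caps.

Prediction: a rule's activation is its weight (the majority-class share
of its training members) times the minimum of its trapezoid memberships;
a class's degree of membership is the maximum activation over its rules;
a compound is attributed to the top class only when that degree strictly
exceeds 0.5, otherwise it is *unpredicted* and excluded from reported
statistics — the same exclusion the reference workflow applies. A
consequence of the trapezoid geometry worth knowing: raw membership
crosses 0.5 at 0.075·w inside each cut, so compounds closer than that to
a decision boundary abstain rather than guess. Class structure separated
by margins wider than the shoulder band is recovered exactly; the
synthetic generator's default boxes keep a 20%-of-range buffer for this
reason.

Ties are broken deterministically (higher score, then subspace, axis and
cut order), and training uses no randomness at all, so a fixed input
yields a bit-identical model.

## Descriptor selection

**Hybrid GA + stepwise (HSA).** Binary chromosomes over descriptors (10
chromosomes, 8 initially active, 1-point crossover at fraction 0.8,
mutation 0.05, rejection of the worst 0.1 with elitism, 10 generations),
followed by stepwise refinement of the best chromosome: add the best
remaining descriptor while the fitness gain exceeds 0.02, then drop the
weakest included descriptor while the loss from dropping stays below
0.02. (Read literally, the drop rule in its source formulation would
remove the *most* useful descriptor; the implementation uses the standard
stepwise semantics.) Fitness is the stratified 5-fold cross-validated
score of a depth-limited AFP — at most 6 subspaces, mirroring the
"cluster number" — with the validation fold up-weighted by 1.5:
`(train + 1.5·validation) / 2.5`. Unpredicted compounds count as errors
inside the fitness so abstention is never rewarded. Inside the fitness
model only, cut candidates are a 9-point quantile grid per axis; the
coarse grid changes selection fitness by far less than fold noise and
keeps the search tractable. Fitness values are cached per chromosome, and
every random draw derives from the single configured seed, so selection
is bit-reproducible.

**Correlation/collinearity filter** (the perceptron branch's route):
greedily drop one member of every pair with |r| > 0.9 (keeping the higher
variance member), then drop the largest variance-inflation factor until
all VIF ≤ 10. The 0.9/10 thresholds are conventional QSAR practice; the
original tool's values are unpublished.

## Perceptron

One hidden tanh layer, tanh output, classes coded ±1, inputs min–max
scaled to −1..1, full-batch gradient descent on mean squared error with a
momentum term. Defaults: learning rate 0.01, momentum 0.7, at most 1000
epochs, early stopping when a stratified 20% validation split has not
improved for 20 epochs, returned weights always those of the validation
minimum. The learning-rule constants are not published; these defaults
are ordinary choices for the rule, and every benchmark in the test suite
passes them explicitly where it needs stronger driving (e.g. the XOR
layout trains with rate 0.1, momentum 0.9). Hidden-layer size is chosen
by exhaustive comparison of mean minimum validation error over repeated
runs — the same criterion the original's genetic search optimises — with
a one-standard-error parsimony rule toward smaller networks.

## Splitting, domain, statistics

The stratified 20% split allocates per-class test seats starting from
`ceiling(0.2 · class size)` and trims, largest fractional remainder
first (ties toward the smaller class), until the total equals
`round(0.2 · n)`. This rule reproduces both published allocations —
34/8 + 133/34 for the 42:167 scheme and 87/21 + 80/21 for 108:101 —
which classical largest-remainder rounding does not (it gives 22/20 for
the balanced scheme).

The applicability domain is the closed per-descriptor training min–max
box; violations are reported per descriptor with a direction. The
published domain table ships as a JSON fixture (`domain_ranges()`).
Statistics follow the standard formulas — accuracy, precision,
sensitivity, specificity and the F-measure as the harmonic mean of the
last two — computed on exact rationals, reported as half-up-rounded
percentages, with zero-denominator ratios surfaced as `NA` rather than 0
or 100. One published inconsistency is worth noting: the reference AFP
training column prints precision 95, sensitivity 96 and F-measure 96,
but the harmonic mean of 95 and 96 rounds to 95; the other three
printed F-measures follow exactly from their precision/sensitivity
pairs, and only those three are asserted by the acceptance suite.

EC3 boundary values (0.1, 1, 10) are assigned to the weaker-potency
side, consistent with the strict `<` convention of the class
definitions; NC arises only from an explicit flag, never from a number.

## Synthetic data: what it emulates, and what it does not

`synthetic_spec()` plants axis-aligned class boxes for 7 informative
descriptors inside the published descriptor-space domain, adds Gaussian
within-box jitter (2% of range), flips 5% of labels, and appends 7
nuisance descriptors correlated 0.6 with informative ones via
`y = ρ·z + √(1−ρ²)·ε`. Defaults mirror the study conditions: 42:167
compounds (the balanced 108:101 variant is one argument away). The
ground truth — boxes, informative set, and a Monte-Carlo Bayes-accuracy
estimate computed from the exact generative densities — is returned
beside the data so recovery tests never re-derive it.

What passing tests on this generator show: the pipeline recovers planted
axis-aligned, box-shaped class structure at realistic imbalance and noise,
without leaking test data, and approaches the known Bayes rate. What they
do not show: performance on real chemistry, where class boundaries are
not axis-aligned, descriptors are discrete or heavy-tailed, and label
noise is not independent of structure. The published headline accuracies
require the original curated compound set and are deliberately not
claimed.

## Numerical choices and degenerate inputs

* Constant descriptor columns: flagged, mapped to 0, never dropped
  silently.
* Test values outside the training range normalize outside −1..1 without
  clipping — the applicability domain, not the scaler, is the guard.
* Zero-width trapezoid intervals degenerate to point indicators.
* Sub-seeds for every stage derive deterministically from one top-level
  seed (a hash of the stage name), so a single integer reproduces a whole
  run; the pipeline manifest records content hashes of every stage output.
* Problem sizes in the test and acceptance suites (e.g. n = 300 for the
  noisy-recovery benchmark, n = 120 with 18 noise descriptors for
  selection recovery, 5 selection seeds) were chosen as the smallest
  sizes at which the planted effects dominate sampling noise.

## Known limitations

* The exact subspace-scoring formula of the original AFP software is not
  public; the local-score/global-gain combination above is this package's
  documented substitute, isolated behind `afp_config()`.
* `EEig10r` and `PCR` conventions are reconstructions constrained by the
  published descriptor-domain table, as described above.
* Aromaticity perception beyond lowercase notation covers only
  six-membered Kekulé C/N rings; five-membered heteroaromatics must be
  written in aromatic form.
* The AFP implementation supports k classes structurally but is exercised
  and validated only on binary problems.
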