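---
title: "Methods: population-graph GCNs and decomposition-based explanations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-graph GCNs and decomposition-based explanations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

`popgcn` classifies the cognitive status of elderly subjects — normal
cognition (NC), mild cognitive impairment (MCI), or Alzheimer's disease
(AD) — from thirteen multimodal clinical features organised in five
modality groups: demographics (age, gender), structural imaging (mean
temporal/precuneus cortical thickness MCT in mm, total hippocampal
volume THV in cm³), cognitive composites (memory MEM, executive
function EXF, language LAN), neuropsychological screens (GDS, MoCA,
MMSE), and biomarker/genetic measures (amyloid-beta and tau positivity,
polygenic hazard score PHS).  Subjects are nodes of a *population
graph* whose weighted edges encode inter-subject similarity; a spectral
graph convolutional network (GCN) performs semi-supervised node
classification, and a decomposition (occlusion) framework explains each
individual prediction at the feature, modality-group, and
neighborhood-edge level, in factual/counterfactual pairs.

Because the clinical source data sit behind restricted access, the
package ships a synthetic cohort generator that reproduces the
published class-conditional summary statistics (per-class means and SDs
of the ten continuous features, categorical proportions for gender and
the two biomarkers, class sizes 754/1095/363).  Every stage of the
pipeline is exercisable, and is tested, on that synthetic cohort.

## The synthetic cohort generator

`default_spec()` encodes the published statistics; `generate_cohort()`
draws from them.  Design choices:

* **Truncated normals with moment-matched parents.**  Continuous
  features are truncated to instrument ranges (MMSE, MoCA, GDS in
  [0, 30]; MCT, THV > 0; age in the enrollment range [55, 90]) and
  sampled by rejection.  The parent mean and SD are fitted numerically
  so that the *truncated* distribution reproduces the published
  moments.  This matters near instrument ceilings: naively sampling
  MMSE for NC subjects as N(29.1, 1.07) truncated at 30 would bias the
  realized mean down by ≈ 0.37 points.  One pair is provably
  unattainable — no normal truncated at 30 can combine mean 29.1 with
  SD 1.07 (the SD-to-headroom ratio exceeds the family's supremum) —
  so the fit prioritises the mean (weight 25:1) and the realized MMSE
  SD for NC/MCI comes out below the printed value.  This is a property
  of the published numbers, not of the sampler: the real data are
  integer-valued and left-skewed at the ceiling, which a normal family
  cannot be.
* **Biomarker orientation.**  The published negative/positive count
  pairs are ambiguous; read literally as +/− they would make only 31 of
  363 AD cases amyloid-positive.  The default orientation makes AD
  predominantly biomarker-positive (Aβ+ 91%, Tau+ 98%), and a flag
  restores the literal reading.
* **Independent features by default.**  The published table carries no
  covariances.  A user-supplied correlation matrix is honoured through
  a Gaussian copula, but the default — and the condition under which
  all reported numbers are computed — is within-class independence.
* **One record per subject.**  The source study pooled repeated visits;
  the generator does not model longitudinal structure.

What passing tests on this cohort do *not* show: the synthetic data are
cleaner than real clinical data (no within-class feature correlation,
no site or phase effects, no repeated visits straddling data splits, no
label noise), so classification metrics here are upper-bound-flavoured
relative to real cohorts, and the published real-data values act as
floors in the acceptance checks.

## Preprocessing

`clean_features()` implements single-pass cleaning: per class and
feature, values outside the 5th–95th percentile band (percentiles
computed once, on the original values) and missing cells are replaced
by a centered moving mean of window length 8 (four clean cells before
and after in stored row order, shrunk at boundaries; the class mean of
clean cells is the fallback for an all-bad window).  Categorical
missing values take the class mode.  Note that this rule, like any
percentile-based rule, is not idempotent on continuous data — a second
application would recompute percentiles on the cleaned column and flag
a fresh 10% tail.  The procedure is defined as one pass; idempotence
holds only on discrete/plateau-valued columns.

`split_dataset()` assigns 80/10/10 train/validation/test *before*
standardization, stratified by class so the 754/1095/363 imbalance is
preserved in every partition (largest-remainder apportionment within
class).  `standardize()` z-scores continuous features using
train-partition statistics only; categorical encodings (Male = 1,
Female = 2; Positive = 1, Negative = −1) are left untouched — a
standardized zero equals the train mean and is therefore informative,
which is also why the masking contract below omits rather than
zero-imputes in the original units.

## The population graph

For each cognitive measure (MEM, EXF, LAN — the measures with known
links to the pathology), pairwise absolute distances on the
*standardized* scores are scaled by the maximum pairwise distance and
subtracted from one (`measure_similarity()`); self-similarity is
defined as zero.  The three matrices are combined by arithmetic mean,
min–max rescaled over the off-diagonal to [0, 1], and entries below
`edge_threshold` (default 0.5) are zeroed (`build_adjacency()`).  The
printed formula combining similarity factors is typographically
ambiguous; the prose description — per-measure similarity, then combine
and normalize — is what is implemented, with the combination rule and
normalization both configurable.  Min–max normalization is global
rather than per measure pair; the source is silent on this and the
global choice keeps weights comparable across the graph.

The propagation operator is the self-looped symmetric normalization
Ã = D̂^(−1/2)(A + I)D̂^(−1/2) (`normalize_adjacency()`), well defined for
any A because self-loops bound degrees below by one.  With the default
threshold the graph is *dense* (mean degree ≈ 1965 of 2212 on the
default cohort): predictions are strongly neighborhood-driven, which is
visible in the explanations (edge-level influences are large, raw
single-feature influences are small) and motivated the fast occlusion
kernel described below.

## The GCN

Two graph-convolution layers (hidden width 32): H₁ = relu(Ã X W₀ + b₀),
logits = Ã H₁ W₁ + b₁, softmax over the three classes.  The residual
term of the layer rule is added only when input and output widths
agree — a residual across a width change is dimensionally impossible,
so with the default 13 → 32 → 3 architecture no residual applies.
Training is transductive: forward passes cover the whole graph,
cross-entropy is evaluated on training rows only, optimized by Adam
(learning rate 0.01, conventional β₁/β₂, 100 epochs), with validation
accuracy recorded every 5 epochs and the best-validation checkpoint
retained (earliest epoch on ties — "validates every five epochs" is
published; checkpoint *selection* is this package's choice).  Weights
are Glorot-scaled uniform draws from the configured seed; everything is
deterministic given the seed.

**Masking contract.**  A masked (node, feature) cell contributes
nothing to any weighted sum it enters — omitted, not renormalized.  An
input cell enters the computation only through the first propagation's
weighted sums, where omission of a term is numerically identical to
zeroing that cell's contribution, which is how it is implemented.
Masked edge groups zero the node's rows/columns of A for neighbors of
one class, after which Ã is *recomputed* (degrees change; silencing
A without renormalizing would be inconsistent with the propagation
definition).

## Explanations

For node x with predicted class y\* and runner-up y′:

* `feature_influences()`: Var_i(y|x) = p(y|x) − p(y|x∖T_i), occluding
  each of the 13 features in turn.
* `group_influences()`: all features of a modality group occluded
  concurrently; with a group of one this reduces exactly to the
  single-feature influence, and group influences are deliberately not
  additive in the member features (they capture interactions).
* `edge_class_influences()`: all edges from the node to neighbors of
  one class silenced, Ã recomputed.
* Positive influence supports the class, negative opposes it; because
  probabilities sum to one, each occlusion's three class-wise
  variations sum to zero, and probability lost by y\* is displaced to
  the other classes — the basis of the counterfactual pairing.  On a
  runner-up tie the clinically adjacent class in NC < MCI < AD order
  wins (earlier class on an exact distance tie); configurable.
* `normalize_influences()` rescales a 13-vector by its mean absolute
  value for display (mean magnitude 1, signs preserved).  The published
  figures show magnitudes near 1–2 without stating the rule; raw
  probability variations are always retained alongside, so the choice
  is cosmetic.
* `discretize_feature()` verbalizes values: GDS and MMSE use published
  clinical cutoffs; other continuous features are binned by signed
  distance from the pooled all-class mean in SD units with boundaries
  −1.5, −0.5, +0.5, +1.0, +1.5 (labels very low … very high; the
  label names are published, the boundaries are this package's
  choice).  For features where lower values are clinically worse
  (MMSE, MoCA, MEM, EXF, LAN, MCT, THV) the sign is flipped before
  binning so labels track abnormality.
* `reference_deviation()` reports each value minus the mean over NC
  subjects of the same gender within ±5 years of age, widening the
  window in 5-year steps (with a warning) when a stratum is empty.

**Fast occlusion kernel.**  Every feature-level occlusion and Shapley
evaluation perturbs a single row of X.  For the 2-layer architecture
the effect on that node's own output factors exactly through its graph
neighborhood, and the neighbor sum Σⱼ aⱼ·relu(Bⱼₕ + aⱼ·d) is piecewise
linear in the perturbation component d with breakpoints −Bⱼₕ/aⱼ.
Sorting breakpoints once per hidden component and keeping suffix sums
reduces a batch evaluation from O(neighbors) to O(log neighbors) per
component — a ~70× speed-up on the dense default graph.  The kernel is
exact (not an approximation) and the test suite verifies it against
full-graph forward passes at 10⁻¹⁰.

## Evaluation suite

* **Stability** (`stability_table()`): for thresholds e ∈ {0.96, 0.94,
  0.90, 0.85, 0.80}, same-class neighbors with edge weight > e are
  collected (neighborhoods are nested by construction), each neighbor's
  display-normalized influences are computed for its *own* predicted
  class (identical to the anchor's class whenever predictions agree,
  which is the typical case), and the per-feature |max − min| across
  the neighborhood is reported.  The anchor itself is not included (a
  single-neighbor neighborhood has distance zero by definition).  The
  published distance table appears rescaled (several rows peak at
  exactly 1.0) by an unstated rule; raw distances are reported, with an
  optional per-feature max-rescale flag.
* **Shapley comparison** (`shapley_values()`,
  `method_agreement()`): Shapley attributions of p(y\*|x) over the 13
  features with absent coalition members replaced by training-row
  values — full enumeration over 2ᵖ coalitions with background
  averaging in exact mode (refused above 20 features), permutation
  sampling with one background draw per permutation in sampled mode.
  The full train partition is the default background (a subsample
  option exists for speed).  Agreement pools (feature, node) pairs per
  predicted class and reports Pearson r plus a sign-agreement rate;
  Pearson r is invariant to the display normalization.
* **Modality ablation** (`modality_ablation()`): a fresh model per
  modality subset per seed through the same pipeline as the main run
  (the all-modalities row therefore equals the main model exactly for
  the same seed).  When the cognitive group itself is removed the graph
  is rebuilt from all retained features — the source never says what it
  did in that case, so the fallback is loud (a message is emitted).

## Numerical choices and degenerate inputs

* All-equal similarity vectors give off-diagonal similarity 1 with a
  warning; a constant combined adjacency rescales to all-ones.
* Rejection sampling guards against vanishing acceptance mass; the
  moment-matching fit carries a barrier keeping ≥ ~1% of parent mass
  inside the truncation bounds.
* Zero train SD, all-absent class×feature cells, empty train
  partitions, unknown nodes/features in masks, and empty modality
  subsets are hard, named errors.
* Probability rows are conserved to 10⁻⁹ under every mask; occluded
  class variations are conserved to 10⁻⁹.
* One master seed fans out to per-stage seeds through a stable integer
  hash, so stages are independently reproducible and all derived seeds
  stay below 2³¹.

## Problem sizes used in the reported computations

The acceptance computations use the full default cohort (2212
subjects): five seeds for the classification metrics (median reported),
and for explanation agreement the first-seed model with up to 50 test
nodes per predicted class, the full train partition (~1769 rows) as
Shapley background, and 2000 permutations per node.  Unit and property
tests run on smaller generated cohorts (≈ 150–400 subjects) and on
hand-built toy graphs where exact enumeration and explicit-loop oracles
are feasible.

## Known limitations

* The generator emulates marginal class-conditional distributions, not
  the dependence structure, visit structure, or measurement noise of
  real clinical data.
* The dense default graph makes single-feature influences small in raw
  probability terms; display normalization compensates, but users
  comparing raw influence magnitudes across graphs with different
  densities should expect scale differences.
* Exact Shapley is exponential in the feature count and deliberately
  refused above 20 features.
* The two published stability quantities that depend on unstated
  rescaling rules are reproduced qualitatively, not numerically.
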