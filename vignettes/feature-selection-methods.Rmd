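---
title: "Selecting discriminative brain network features with a GA-wrapped SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting discriminative brain network features with a GA-wrapped SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netselect)
```

## The model

`netselect` classifies two within-subject brain states from nodal graph
metrics of functional connectivity networks and, at the same time, selects
the regions whose metrics carry the discrimination.  The pipeline is:

1. **Connectivity.** For each subject and condition, Pearson correlations
   between all pairs of regional time courses are Fisher-z transformed
   (`z = atanh(r)`), giving a symmetric `d × d` matrix with zero diagonal.
   Correlations are clamped to `|r| ≤ 1 − 10⁻⁷` before `atanh` so that
   duplicated signals degrade to a large finite z instead of `Inf`.
2. **Graphs.** Only positive connections define edges: `a_ij = 1` iff
   `z_ij > τ`, with `τ = 0` by default.  Negative correlations are
   dropped, never absolute-valued, and graphs are binary: degree is a
   count of links, clustering the fraction of closed neighbour pairs,
   betweenness the number of shortest paths through a node (raw counts by
   default; unreachable pairs contribute 0, endpoints are excluded, and a
   `normalized` flag divides by `(d−1)(d−2)/2`).  Clustering at degree
   < 2 is defined as 0 so feature vectors stay finite.
3. **Features.** One table per metric: rows are subject × condition
   samples, columns are regions.  Every subject contributes exactly one
   sample per condition, so the two classes are balanced by construction
   and plain accuracy is an unbiased summary.
4. **Classifier.** A soft-margin C-SVM with RBF kernel (LIBSVM via
   e1071).  Accuracy is estimated by leave-one-subject-out
   cross-validation: both samples of the held-out subject leave together,
   which is what prevents subject-identity leakage.  Features are z-score
   standardized per fold with means and SDs estimated on the training
   fold only.  Hyperparameters are grid-searched over powers of two,
   `C ∈ {2⁻⁵, 2⁻³, …, 2¹⁵}`, `γ ∈ {2⁻¹⁵, 2⁻¹³, …, 2³}`; ties are broken
   to the smallest `C`, then the smallest `γ`.
5. **Selection.** The wrapper objective is `max f(x)` over binary masks
   `x ∈ {0,1}^d`, where `f` is the grid-searched LOSOCV accuracy of the
   masked table.  A generational genetic algorithm searches the mask
   space; the significance baseline (`manual_select()`) instead keeps the
   regions whose metric increased significantly from the low- to the
   high-load condition (one-sided paired t-test, `p < α = 0.05`,
   uncorrected) and reports the grid-searched LOSOCV accuracy of that
   fixed set.

Group-level network structure is summarized descriptively (it is not a
classification feature) by Newman modularity of the group-averaged
positive graph, computed with igraph's leading-eigenvector method — the
spectral algorithm of the modularity literature, without the optional
Kernighan–Lin refinement pass.  Spectral partitioning is not guaranteed
optimal, so the package asserts only that the reported `Q` is consistent
with the reported assignment and never exceeds the exhaustive-partition
optimum on small graphs.

## Genetic algorithm

Defaults follow the standard parameterization of this wrapper: population
100, 100 generations, two-point crossover with rate 0.7, tournament size
4, per-individual mutation probability 0.5.  Two details deserve
explanation because the conventions differ between GA frameworks:

* **Mutation.** "Mutation rate 0.5" is the probability that an
  *individual* enters mutation; once it does, each gene flips
  independently with probability `1/d`.  A per-gene rate of 0.5 would
  re-randomize half of each chromosome every generation and no selection
  signal would survive.
* **Ties.** Tournament ties go to the earliest-drawn aspirant, which
  makes selection under all-equal fitness an exactly uniform resample — a
  property the test suite checks by a chi-square goodness-of-fit test.
  Best-ever ("hall of fame") tracking records the fittest mask ever
  evaluated; at equal fitness the *smaller* mask wins.  This parsimony
  tie-break matters in practice: when the planted effect is strong, many
  masks tie at the accuracy ceiling and the tie-break is the only
  pressure toward reporting a mask without superfluous regions.  It is a
  tie-break only — there is no sparsity term in the objective.

Pairing for crossover is consecutive pairs of the shuffled selected
population; replacement is generational (no elitism inside the
population, the returned optimum is the best-ever individual).  Fitness
values are cached by mask, since LOSOCV × grid search is the cost
bottleneck and masks recur as the population converges.

Fitness evaluation inside the GA uses a coarse 3 × 3 subgrid
(`C ∈ {2⁻¹, 2³, 2⁷}`, `γ ∈ {2⁻⁹, 2⁻⁵, 2⁻¹}`) and the final report
re-evaluates the best mask on the full grid.  Running the full grid
inside every fitness call is supported (`fitness_grid = hyper_grid()`)
but slows the search by an order of magnitude.  Note that grid search by
LOSOCV accuracy *is* the objective being maximized (non-nested), so
reported accuracies are optimistically biased as estimates of
out-of-sample performance; the GA-vs-baseline comparison is still fair
because both arms are reported the same way.

The empty mask is assigned fitness 0 rather than raising, so the GA can
generate and discard degenerate individuals freely.

## The synthetic cohort generator

No imaging data ships with the package; `simulate_cohort()` provides
ground-truth cohorts in two modes.

**Network mode** draws a base inter-regional correlation matrix from a
5-factor model (plus a common factor calibrated by root-finding so the
expected positive-edge density matches `base_density`, default 0.6, a
typical share of positive correlations in Fisher-z connectivity
matrices).  Per subject, factor loadings are jittered at scale
`subject_sd`; in the high condition the configured `effect` (default
0.3, correlation units) is added to every correlation incident to a
planted region, entries are clamped to ±0.995, and the matrix is
repaired to the nearest valid correlation matrix by eigenvalue clipping
(floor 10⁻⁸, rescale to unit diagonal).  An effect that saturates most
affected correlations is refused with a pointer to reduce it.  Each
subject × condition then yields `T` i.i.d. multivariate-normal
timepoints.

**Feature mode** emits the metric table directly:
`value = μ_r + b_sr + δ·1[r planted, condition B] + ε`, with
`ε ~ N(0, 1)` the within-subject noise and `b_sr ~ N(0, subject_sd)` a
region-specific subject intercept shared by the subject's two conditions
— the exchangeable within-subject correlation that paired tests assume.
`subject_sd` defaults to 1.0: test–retest studies of nodal graph metrics
put their ICC near 0.5, i.e. between-subject variability comparable to
within-subject variability.  The intercepts cancel exactly in the paired
t-test but *not* in the sample-level SVM, which is what makes held-out
subjects genuinely hard and gives the wrapper something to optimize.

Default dimensions are desk-scale: `d = 40` regions, `n = 28` subjects,
`T = 150` timepoints, 10 planted regions (full `d = 116` is supported,
just slower).  What the generator does **not** emulate: hemodynamics,
autocorrelated BOLD noise, motion artifacts, atlas misparcellation, and
scanner drift.  Passing tests on these cohorts therefore demonstrate the
correctness of the machinery and the behaviour of the method under
idealized planted effects — not expected accuracy levels on real fMRI
data.

At the default feature-mode settings the planted effect is strong
(`δ = 1.5` within-subject SDs across 10 regions), and LOSOCV accuracy of
many masks saturates at 1.0.  Two consequences, both visible in the test
suite: the GA reliably matches or beats the manual baseline, but once at
the ceiling it has no gradient to shed noise regions, so the returned
mask is only partially enriched for the planted set.  That is a property
of wrapper selection without a sparsity objective, not an implementation
artifact.

## Numerical choices and degenerate inputs

* Correlation clamp `1 − 10⁻⁷` before `atanh`; configurable.
* Zero-variance regions are rejected at load, naming the region.
* `τ` must be ≥ 0 (a negative threshold would re-admit negative edges).
* Edge rule is strictly `z > τ`, so at `τ = 0` a zero correlation is not
  an edge.
* Modularity on an edgeless graph is an error, not NA.
* Fold standardization guards `sd < 10⁻¹²` by substituting 1 (a feature
  constant in a training fold contributes nothing after centering).
* SVM training uses e1071's LIBSVM engine.  By default the package calls
  the registered native trainer directly after a one-time probe that the
  direct path reproduces `e1071::svm()` exactly (support vectors,
  coefficients, rho, label order); if the probe fails the package falls
  back to the public interface.  Predictions are computed from the
  support-vector expansion and the test suite asserts exact agreement
  with `predict.svm` across random problems.
* Grid-search ties: smallest `C`, then smallest `γ` — deterministic
  reporting of the least-regularizing ambiguous choice.
* All stochastic entry points (`simulate_cohort()`, `ga_select()`,
  `run_pipeline()`) take explicit integer seeds; the pipeline report is
  byte-identical across reruns with the same config and seed.

## Problem sizes used in the validation suite

Graph-metric oracle checks run on ≥ 100 random graphs with `d ≤ 12`
against exhaustive enumeration (triangles counted over node triples,
shortest paths counted by matrix powers); modularity soundness on 50
connected graphs with `d ≤ 8` against all set partitions (Bell(8) =
4140).  Classifier-protocol checks use 8–10 subject tables and 200 label
permutations.  The GA-versus-baseline comparison runs 10 paired planted
cohorts at `d = 40`, `n = 28`, `δ = 1.5`, GA population 30 × 30
generations; the baseline-power check runs 100 cohorts at the same
conditions.  These sizes were chosen so the whole suite validates every
stage in a few minutes on a single core while keeping each statistical
check adequately powered.

## Limitations

* The reported accuracy is a model-selection criterion, not an unbiased
  generalization estimate (non-nested grid search; wrapper selection).
  Nested CV is the standard remedy and can be emulated by holding
  subjects out before calling `ga_select()`.
* GA solutions are stochastic; different seeds can return different
  region sets of equal fitness.  Stability should be assessed across
  seeds (`run_pipeline()` records the seed of every run).
* Binary graphs at `τ = 0` follow the positive-connections convention;
  weighted-graph metric variants are a possible extension and would
  change the feature values, not the selection machinery.
* Only two-state, within-subject designs are supported (one sample per
  subject per condition).
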