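---
title: "Stratifying constitution types from categorical questionnaire phenotypes"
author: "PrakritiML"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying constitution types from categorical questionnaire phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Ayurvedic practice classifies healthy individuals into constitution types
(*Prakriti*). Three types — *Vata* (V), *Pitta* (P) and *Kapha* (K) — sit at
the extremes of the phenotypic spectrum; the remaining types (VP, PK, VK) are
regarded as mixtures of two extremes. Clinicians assign these labels from a
questionnaire of more than a hundred categorical traits whose interpretation
is combinatorial: single traits are rarely decisive, combinations are.

Statistically this is a small-*n*, large-*p* problem on unordered categorical
data with strong inter-trait correlation. PrakritiML implements a complete
analysis for it:

1. **Unsupervised structure discovery.** Do the extreme types emerge as
   clusters from the trait data alone, without using the labels?
2. **Supervised classification.** Can a compact subset of traits predict the
   label, and does a model trained on one cohort transfer to another?
3. **Two-stage screening.** Can extreme individuals be separated from
   mixture individuals using only the extreme-class model's output?

Because the questionnaire cohorts this kind of study rests on are not
publicly deposited, the package ships a seeded synthetic-cohort generator
that reproduces the study design's *shape* — sample sizes, feature counts,
class imbalance, correlated trait blocks, missingness — so that every stage
is testable end to end.

## The synthetic cohort generator

`cohortSpec()` describes a generative model; `generateExtreme()`,
`generateNonExtreme()` and `deriveSecondCohort()` draw cohorts from it.
Identical spec and seed reproduce a cohort byte for byte.

The default spec mirrors the study conditions the package's checks are
calibrated on: 147 extreme samples (66 V / 35 P / 46 K), 106 mixtures split
40/33/33 over VP/PK/VK, 133 categorical features with 2–4 levels of which
the first 80 are class-informative, 12 contiguous correlated blocks, signal
strength 0.85, block coupling 0.5, 3% missingness, and a 96-sample second
cohort sharing the first 106 features. A scientist wanting other regimes
changes the spec, not the code.

The generative mechanism:

* Every informative feature gives each class a **preferred level** that
  cycles deterministically with the class index, so 2-level features cannot
  separate three classes on their own — as in real questionnaires, traits
  are combinatorially rather than individually decisive.
* The class-conditional distribution puts mass `signalStrength` (*s*) on the
  preferred level and spreads the remainder uniformly. When *s* is at or
  below the uniform baseline 1/L no preference is expressible and the
  distribution is uniform over all levels; this makes `signalStrength = 0`
  an exact null in which every feature is identically distributed across
  classes.
* Features are partitioned into contiguous **blocks**. Per sample and
  block, one latent uniform is drawn; each informative feature copies it
  with probability `blockCoupling` (inverse-CDF sampling then induces
  within-block concordance). Because coupling copies the block's latent
  *preference* draw, features without an expressible preference (s at or
  below 1/L) sample independently — a zero-signal cohort is therefore
  exchangeable with its column permutations, which is exactly the null the
  permutation analysis below assumes.
* **Mixture samples** with parents (A, B) draw each feature from A's
  class-conditional distribution with probability 1/2 and from B's
  otherwise, independently per feature. No block coupling is applied to
  mixture draws; the spec of the mixture mechanism is feature-independent
  by construction. Marginally, a mixture's probability of showing A's
  preferred level is the exact average of the two parents' probabilities,
  which is what places mixtures between their parent clusters.
* Missingness is injected completely at random (`injectMissing()`), as
  nothing in the study design characterizes a more structured mechanism.

What the generator does **not** emulate: real trait semantics, ordinal
structure, sex and age effects, informative missingness, or
cluster-number heterogeneity between subgroups. Tests passing on these
cohorts show the pipeline recovers planted structure of the stated kind and
strength; they cannot certify performance on real questionnaires.

## Preprocessing

`preprocessPhenotypes()` applies, in order: removal of features whose
missing fraction **strictly exceeds** 5% (a feature at exactly 5% is kept),
imputation of remaining missing cells by the feature's **mode** (ties broken
toward the lexicographically smaller level, a determinism choice), and
removal of non-varying features. Dropping constants *after* imputation means
a feature made constant by imputation is also removed. The pipeline is
idempotent, preserves feature order, and returns a `PreprocessReport` whose
removed and retained sets partition the input.

## Unsupervised clustering with a permutation null

`rfDissimilarity()` builds the unsupervised random-forest dissimilarity: a
synthetic contrast cohort is created by independently permuting every
feature column (`syntheticContrast()`, preserving marginals, destroying all
joint structure), a classification forest learns to separate real from
contrast samples, and the proximity of two real samples — the fraction of
trees in which they share a terminal node — becomes the dissimilarity
`1 − proximity`. Proximity is counted over all trees by default
(`oobProx = TRUE` restricts it to jointly out-of-bag trees). The default
forest size is 10,000 trees, which keeps a desk-scale run in seconds while
leaving the proximity estimates stable to within a few hundredths; the
size is configurable upward for production runs.

`pamClustering()` performs k-medoid clustering on that dissimilarity and
`selectK()` chooses the number of clusters by maximal average silhouette
width over k = 2..20, ties to the smallest k. Two numerical choices are
worth noting:

* Instances with a small medoid-set space (`choose(n, k) ≤ 3000`) are
  solved **exactly** by deterministic exhaustive enumeration. PAM's
  BUILD+SWAP is a local search; on small awkward instances it misses the
  global optimum roughly one time in ten, so where the exact optimum costs
  only a few thousand objective evaluations the package computes it.
  Study-scale problems (n = 147, k = 2..20) use classic BUILD+SWAP via
  `cluster::pam`, which is deterministic given the dissimilarity.
* Silhouette widths follow the standard definition with the singleton
  convention s(i) = 0; `k = 1` has no silhouette and is never selected.

`savannah()` is the cluster-validity null: each of `nPermutations`
replicates independently permutes every feature column (replicate seed =
master seed + replicate index, so replicates are reproducible in isolation),
recomputes the forest dissimilarity and the silhouette profile over k. Real
joint structure shows as the original profile standing far above the
permuted envelope. The replicate forests default to 2,000 trees — the
permuted widths are flat and need less averaging than the original
profile. Note one irreducible calibration fact: for a truly structureless
cohort the original width is exchangeable with the permuted ones, so it
falls outside a 20-replicate min–max envelope with probability about 2/21
on any given seed.

`clusterLabelAgreement()` scores a partition against the clinician labels as
the best one-to-one cluster-to-class mapping on the contingency table,
found with an exact Hungarian assignment solver (written in-package, as no
assignment solver is among the dependencies; verified against exhaustive
permutation search). `classicalMDS()` provides metric multidimensional
scaling with a fixed sign convention (first nonzero loading positive) and
explicit dropping of negative-eigenvalue axes.

## Supervised classification

All three classifiers share one stratified 90/10 split
(`splitTrainTest()`). Per-class test counts are the nearest integer to 10%
of the class size (halves up), which reproduces the canonical 16-sample
hold-out of 7 V / 4 P / 5 K on the default cohort.

**LASSO and elastic net** (`fitLasso()`, `fitEnet()`, via `glmnet`) fit
penalized multinomial regressions on the dummy-coded traits
(`encodeDesign()`; reference level = modal level, ties lexicographic;
levels unseen at training time score as the reference). λ runs down a
100-step logarithmic path from λ_max to λ_max·10⁻⁴ and is chosen by
stratified 10-fold cross-validated **misclassification error**, ties toward
the larger λ. The elastic net adds the canonical 11-point α grid 0, 0.1, …,
1, with α = 0 floored to 0.01 because a pure ridge penalty never performs
selection; ties go to the larger α then larger λ. Ties toward stronger
regularization make the selected models deliberately parsimonious: on
near-separable cohorts the cross-validated error reaches its minimum over a
wide λ range and the largest such λ retains only a minimal predictive
subset of the informative features. That is the intended behavior of these
selectors — they find a *sufficient* feature set, not the complete planted
set — and the package reports, but does not promise, high recall of all
informative features for the penalized methods.

**Random forests** (`fitForest()`) first run a shadow-feature relevance
filter (`borutaSelect()`): each run appends an independently permuted
shadow copy of every still-active feature, fits a forest with permutation
importance, and scores a hit for a real feature beating the maximum shadow
importance; hit counts are tested against Binomial(runs, ½). The binomial
decisions are Bonferroni-adjusted across the features under test — the test
is applied after every run, and without the adjustment this sequential
testing confirms noise features well above the nominal level. Features
undecided at `maxRuns` are resolved by comparing their median importance to
the median shadow maximum. Two behaviors of this procedure on correlated
data are worth knowing: confirmed features stay in the model (they are not
dropped from shadowing), and correlated block-mates can carry each other
over the shadow maximum, so a few false confirmations per hundred features
are expected even under a label permutation.

`tuneForest()` then tunes the forest on the confirmed set with the grid
protocol: twenty tree counts (500 to 10,000 by 500), five refits each,
scored by least median out-of-bag error with least standard deviation and
then the smaller value as tie-breaks; the same protocol tunes `mtry` over
1..min(15, ⌈√p⌉+10) at the chosen tree count.

`evaluateModel()` predicts by maximum class probability (ties to the sorted
class order K, P, V) and reports the confusion matrix with one-vs-rest
sensitivity and specificity. `harmonizeFeatures()` +
`crossCohortValidate()` implement external validation: restrict both
cohorts to shared features, retrain on 90% of one, evaluate on all of the
other; the reverse direction is the same call with the cohorts swapped.

## Two-stage extreme vs non-extreme classification

`probabilityMaxima()` scores every sample by the maximum of its predicted
class-membership probabilities. Extreme samples concentrate probability on
one class (maxima near 1); feature-wise mixtures split it between their two
parents (maxima nearer ½). `fitBinary()` regresses the binary extreme
indicator on this scalar score — a deliberate one-covariate logistic model,
fit by Newton iterations to tolerance 1e−8. Perfect separation (where the
logistic MLE diverges) is detected and refit with a tiny L2 ridge (1e−6),
flagged in the result. A configuration that regresses on all K class
probabilities instead of the scalar maxima was considered and rejected:
the scalar model matches the method's design and keeps the second stage
interpretable as a single probability threshold (0.5 posterior by default;
nothing in the study design prescribes another).

`twoStageClassifier()` builds, per base method, ten candidate logistic
models differing only in their cross-validation fold seed, keeps the one
with the best mean 10-fold CV accuracy (ties to higher AUC,
`selectBestTwoStage()`), and reports sensitivity and specificity from the
winner's *out-of-fold* posteriors — honest estimates, not resubstitution.
The AUC is the exact Mann–Whitney U statistic (ties counted half) computed
from midranks.

## Problem sizes used by the packaged checks

The test suite and the acceptance script run the whole pipeline at the
default study shape: dissimilarities from 10,000-tree forests,
20-permutation Savannah nulls at 2,000 trees, the full 20-point tree grid
with 5 repeats for forest tuning, and all three classifiers on the
147-sample cohort with cross-cohort validation on the 96×106 second cohort.
These sizes were chosen so a complete run finishes in minutes on one core
while every estimate is already stable at the tolerances being checked;
all of them are plain arguments for users who want production-scale runs
(up to the million-tree forests of a full analysis).

## Known limitations

* The generator's blocks are contiguous and equally sized; real trait
  correlation is patchier.
* Mixture samples mix exactly two parents with equal weight; three-way
  (VPK) constitutions are not generated.
* The penalized selectors' feature recall is intentionally minimal (see
  above); use the shadow-feature selection when completeness of the
  relevant set matters more than parsimony.
* Agreement, silhouette and PAM are exact or deterministic, but forest
  dissimilarities are Monte-Carlo estimates: two forests with different
  seeds differ element-wise by a few hundredths at 10,000 trees.
* Sex-stratified analyses are supported only by subsetting the cohort and
  rerunning the pipeline; no separate machinery is provided.
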