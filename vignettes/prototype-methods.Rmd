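---
title: "Deriving replicable Big Five personality prototypes"
author: "persotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving replicable Big Five personality prototypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persotypes)
```

## The problem

Person-centered personality research asks whether people cluster into a
small number of recurring Big Five *profiles* — personality prototypes such
as the resilient, overcontroller, undercontroller, reserved and
confident/vulnerable-resilient types — rather than merely varying along five
independent trait dimensions. Answering this with cluster analysis faces two
chronic difficulties: (i) almost any clustering algorithm will return *some*
partition, so the number of clusters and the algorithm must be selected by
explicit, replicable criteria; and (ii) agreement-based selection criteria
are biased toward small numbers of clusters, so several criteria with
different biases have to be combined.

`persotypes` implements a complete selection pipeline addressing both
points:

1. **Split-half replication.** The sample is randomly permuted
   `n_resamples` times and split into halves; three clustering algorithms
   (Ward-initialized k-means, Gaussian-mixture latent profile analysis,
   normalized spectral clustering) are fit on each half for every candidate
   cluster count `k`.
2. **Classifier-based reclassification.** Each half's members are
   re-allocated by one-vs-rest RBF-kernel support vector machines trained
   on the *opposite* half's solution, and agreement between a half's own
   partition and its SVM-predicted partition is scored with Cohen's kappa
   (after optimal label alignment), the Rand index and the Hubert–Arabie
   adjusted Rand index. SVMs rather than nearest-centroid allocation are
   essential: centroid allocation always produces spherical, evenly shaped
   regions, so it penalizes exactly the non-spherical solutions that
   spectral clustering and mixture models are chosen for. On a
   two-rings construction the package reproduces the diagnostic signature:
   nearest-centroid *self*-reallocation of a spectral solution has kappa
   strictly below 1 while SVM self-reallocation is essentially perfect.
3. **The kappa gate.** External criteria are averaged per `k` across
   algorithms; cluster counts with mean kappa below the gate (default 0.6)
   are discarded.
4. **The validity battery and vote counting.** Surviving `(algorithm, k)`
   solutions are refit on the full sample and scored on nine internal
   indices — C-index, Baker–Hubert Gamma, G+, the generalized Dunn index
   GDI31, point-biserial, mean silhouette, S_Dbw, and a
   classification-likelihood AIC and BIC — plus the three external
   criteria. Each index votes for its best solution within each algorithm
   and across algorithms; the winner has the most between-algorithm votes,
   with ties broken by within-algorithm votes and then by smaller `k`.
5. **Labeling and validation.** The winning centers are named by minimal
   profile-similarity D (Euclidean distance in trait z-space, after
   Cronbach and Gleser) against a reference prototype table; stability is
   assessed by re-clustering a second assessment wave and comparing the
   D-matched partition against SVM allocation from the reference solution;
   predictive validity correlates the person-level (inverse) distance to
   each prototype with external criterion variables.

## The synthetic panel generator

The original person-centered analyses of this kind run on restricted-access
longitudinal panel data that cannot be redistributed. The package therefore
ships a generator that emulates the relevant structure of such a panel so
that every stage of the pipeline is testable end to end:

* persons are drawn from a five-component Gaussian mixture in trait
  z-space, with default mixing proportions (0.144, 0.173, 0.246, 0.225,
  0.212) matching the reported prevalences of the five types;
* each trait maps to three 7-point Likert items (rescaled to the item
  midpoint/range, independent Gaussian item noise, optional reverse-keyed
  items, round-and-clip);
* response pathologies are planted: a configurable fraction of careless
  responders answering uniformly at random — the mechanism that maximally
  inflates within-trait answer variance — and missing-completely-at-random
  cells;
* criterion variables are linear combinations of the trait z-scores plus
  Gaussian noise, with coefficients solved from a target trait-correlation
  vector and the empirical trait covariance (targets whose implied
  R-squared exceeds 1 are rejected as infeasible).

What the generator does **not** emulate: longitudinal trait drift between
waves (a "new wave" is a fresh draw from the same population),
non-MCAR missingness, item-level factor structure beyond one latent trait
per item triplet, and response styles other than uniform careless
answering. Passing tests therefore demonstrate that the pipeline recovers
planted structure under these idealized conditions, not that any real panel
contains five types.

### Calibration of the planted prototypes

Published type profiles are described verbally (e.g. resilients pair low
neuroticism with high values on all other traits) but their magnitudes vary
across studies, so the default profiles are sign/shape patterns scaled by a
single `magnitude` parameter. Two considerations fix the default geometry:

* **Recoverability.** At the default magnitude (0.8 z) and within-component
  spread (0.4–0.5 z), k-means at the true `k` recovers the planted labels
  with adjusted Rand above 0.8 — the precondition for any downstream test
  to be informative. At 0.6 z the closest pair of prototypes (resilient vs
  vulnerable-resilient, which differ mainly on neuroticism) blurs and
  recovery drops below that bound.
* **Merge ambiguity.** Split-half replication discriminates between cluster
  counts only if too-coarse solutions are actually unstable. If one merge
  is unambiguously cheapest, the 4-cluster solution is as replicable as the
  5-cluster one and the external criteria tie at their ceiling. The default
  geometry therefore gives the overcontroller *two* nearly equidistant
  merge partners (undercontroller at D = 1.54, reserved at 1.65) alongside
  the resilient/vulnerable-resilient pair at 1.60 — consistent with the
  verbal descriptions (undercontrollers' neuroticism deviates slightly
  from average; reserveds' neuroticism is below average but not extreme) —
  so that halves disagree about which merge to make at k = 3 and 4 while
  the 5-cluster solution remains anchored by the true components.

The replication protocol's own demonstrations run on the latent trait
z-scores the generator plants. Item scoring adds measurement noise
(item noise plus Likert discretization) that attenuates all profiles
uniformly; that noise penalizes finer solutions across the board and is a
property of the measurement model, not of the clustering protocol under
study. The item pathway is exercised separately by the scoring, exclusion
and labeling tests.

## Preprocessing rules

* Trait score = mean of the available keyed items (reverse-keyed items
  flipped as `levels + 1 - value` first); a person missing one item of a
  trait is scored on the remaining two; all three missing gives a missing
  trait.
* Exclusion: more than one missing item answer, **or** intradimensional
  answer variance strictly greater than four times the sample average.
  "Intradimensional answer variance" is operationalized as the mean over
  the five traits of the population variance (denominator 3) of the
  trait's three items; traits with fewer than two available items are
  skipped; the sample average is computed over all persons with a
  computable value *before* any exclusion. On synthetic data with planted
  uniform careless responders this rule's sensitivity exceeds 0.9.
* Z-standardization uses the analysis sample's own moments by default; a
  later wave can be projected with the derivation wave's moments
  (`zstandardize(..., reference = )`), and both modes are supported
  because published analyses rarely state which was used.

## Numerical and algorithmic choices

* **Distances.** Euclidean on the five trait z-scores, everywhere.
* **Ward + k-means.** `hclust(method = "ward.D2")` cut at `k`; cluster
  means seed a single Lloyd run (tolerance 1e-6 on center movement, at
  most 300 sweeps). An empty cluster during a Lloyd sweep is repaired by
  promoting the point farthest from its current center to a singleton
  center; repairs are counted in `fit_extras`.
* **Latent profile analysis.** Gaussian mixtures via EM over four
  covariance families (equal-volume spherical, varying spherical,
  diagonal, full — mclust's EII/VII/VVI/VVV), best family by BIC,
  assignment by maximum posterior. Degenerate EM fits are retried under a
  regularizing conjugate prior (a variance floor). For large halves the
  agglomerative EM initialization runs on a random subset
  (`lpa_init_subset`, default 500), a standard cost-control that leaves
  the EM itself on the full half.
* **Spectral clustering.** Ng–Jordan–Weiss: RBF affinity with bandwidth
  defaulting to the median pairwise distance (suitable for compact,
  blob-like trait profiles; manifold-like data wants a smaller, user-set
  bandwidth), zero diagonal, symmetric normalized Laplacian, top-k
  eigenvectors row-normalized, k-means with 10 restarts. A disconnected
  affinity graph (possible when the Gaussian weights underflow) is an
  error advising a larger bandwidth.
* **SVM reclassification.** One-vs-rest soft-margin SVMs, RBF kernel,
  `C = 1`, kernel coefficient `1 / (5 * mean feature variance)` of the
  training half; the test person goes to the cluster with the largest
  decision value. If any training cluster has fewer than two members the
  whole allocation falls back to nearest centroid so decision values stay
  on one scale.
* **Pair-comparison indices.** `s_plus`/`s_minus` are computed by sorting
  the between-cluster distances and counting with binary search — exactly
  equivalent to the quartic-time double loop, which serves as the test
  oracle. Tied comparisons count in neither direction. Gamma is undefined
  (reported missing) when all comparisons tie; the C-index is defined as 0
  when all pairwise distances are equal; GDI31 is undefined when every
  cluster is a singleton; S_Dbw follows the original
  Halkidi–Vazirgiannis formulation (cluster scatter plus midpoint
  density with the average-standard-deviation radius).
* **AIC/BIC for hard partitions.** A classification likelihood with
  Gaussian components at the cluster means, shared spherical variance
  equal to the pooled within-cluster variance, and
  `p = 5k + 1 + (k - 1)` parameters; LPA solutions use their own mixture
  likelihood and parameter count.
* **Label alignment.** Kappa between independently labeled partitions is
  computed after an optimal one-to-one assignment on the (padded)
  contingency table; Rand and adjusted Rand need no alignment. Degenerate
  cases are defined explicitly: kappa on a single shared category is 1
  iff the partitions are identical; adjusted Rand with a zero correction
  denominator likewise.
* **"Inverse distance" similarity.** The person-level similarity to a
  prototype is `-D` by default: any strictly decreasing transform
  preserves the sign structure of correlations, and the negation keeps
  magnitudes interpretable; `1/(1 + D)` is available as an option.

## Problem sizes used in the shipped checks

The package's end-to-end demonstrations run at sizes chosen to exercise the
full protocol while remaining comfortable on a single CPU: the replication
demonstration uses n = 4,000 persons, 20 resamples, k = 3..10 and all three
algorithms; the model-selection consistency check repeats the full
pipeline across 10 protocol seeds at n = 2,000 with 4 resamples and
k = 3..6; stability and labeling checks use waves of 3,000–4,000; criterion
calibration uses n = 14,048, the scale at which a ±0.03 recovery tolerance
corresponds to about 3.5 standard errors of a correlation.

## Known limitations

* The vote count weights all twelve indices equally; no index weighting or
  significance testing of vote differences is attempted.
* S_Dbw values are scale-dependent in their own right and are compared
  only within a selection run, never across data sets.
* The stability comparison assumes both waves cluster into the same `k`;
  a mismatch is matched on the smaller count with unmatched types flagged.
* Reference prototype tables shipped with the package are synthetic
  sign-pattern profiles, not literature values; labeling against the
  literature requires a user-supplied table.
* With strongly overlapping prototype pairs the profile similarities to
  different prototypes are themselves correlated, which limits
  regression-style decompositions of predictive validity; the package
  reports correlations only.
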