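---
title: "Landmark-based facial shape analysis and syndrome classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based facial shape analysis and syndrome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphodx)
```

## The problem

Many genetic syndromes alter craniofacial morphology, and 3D facial
photogrammetry captures that signal as a set of homologous landmarks per
subject. morphodx implements the statistical machinery to go from raw
landmark configurations to syndrome diagnoses and the descriptive statistics
that explain classification performance: Procrustes superimposition,
object-symmetry decomposition, age/sex standardization, Procrustes MANOVA,
regularized discriminant classification with family-aware cross-validation,
per-syndrome shape-space statistics, and the analysis of ostensibly
unaffected relatives.

The distribution of 3D facial shapes is well approximated by multivariate
Gaussians in the tangent space of shape space, which is what makes parametric
discriminant methods appropriate here, in contrast to the deep-learning
pipelines favoured for 2D photographs.

## Shape preprocessing

**GPA.** Configurations are centred, scaled to unit centroid size, and
iteratively rotated onto the consensus (proper rotations only; reflections
are never admitted). Convergence tolerance is 1e-10 on the consensus with at
most 100 sweeps; in practice a handful of sweeps suffice. The superimposition
frame is defined only up to a common rotation, so identities about aligned
shapes are stated in terms of Procrustes distances, not raw coordinates.

**Distances.** "Procrustes distance" throughout is the partial Procrustes
(tangent-space Euclidean) distance between unit-size aligned shapes. The
pairwise function `procrustes_distance()` re-optimizes the rotation between
its two arguments; the cohort-level statistics (severity, distinctiveness,
within-syndrome variance, relative extremeness) use Euclidean distances in
the common superimposition frame, which is the same quantity at the small
shape distances involved and makes algebraic identities (variance = trace of
the coordinate covariance) exact.

**Symmetry.** Facial asymmetry is noise for most syndromic signals, so the
classification input defaults to the symmetric component of shape. The
object-symmetry decomposition jointly superimposes each configuration with
its reflected, relabelled copy, rotates the joint consensus into an exactly
mirror-symmetric frame (computed from the eigenstructure of the
reflect-relabel operator applied to the consensus), and splits each shape
into `(x + reflect(x))/2` and `(x - reflect(x))/2`. The decomposition is
exact: the two parts sum to the aligned shape, and the symmetric part is
invariant under reflect-relabel to numerical precision. Unsymmetrized and
combined (symmetric + asymmetric) inputs remain available via
`prepare_shapes(use = ...)`; the package takes no position on which input
wins on a given data set.

**Outliers.** Two statistics per subject: Procrustes distance to the
consensus, and the variance across landmarks of the per-landmark deviation
magnitudes. Both are standardized by robust z-scores (median/MAD); the
deviation-variance statistic is strongly right-skewed, so its z-score is
computed on the log scale. No numeric threshold is canonical, so the default
cut (z = 3) is deliberately conservative and `sweep_outlier_threshold()`
rescans classification accuracy across cuts, which is how the threshold
should be chosen in practice.

**Age and sex.** Shape is regressed on an orthogonal cubic polynomial in age
plus a centred sex contrast (female = -1/2, male = +1/2); orthogonal
polynomials improve conditioning and their basis parameters are stored so a
fitted model standardizes new data reproducibly. One pooled model across all
groups is the default (`standardize_pooled = TRUE`); fitting on unaffected
subjects only is available as a switch. Subjects missing age or sex are
excluded from standardization and classification with a warning. All
classification runs on the standardized residuals (plus the consensus, to
keep rows interpretable as shapes).

## Variance attribution

`procrustes_manova()` computes sequential (type-1) Procrustes sums of
squares. Because entry order is arbitrary in non-orthogonal designs, the SS
are averaged over every ordering of the terms (enumerated up to 6 terms,
a seeded sample of 720 orderings beyond that). F statistics are Goodall-style
ratios of mean squares; p-values come from residual randomization under the
reduced model that omits the term in question, with
`p = (1 + #{F* >= F}) / (1 + n_perm)` and a default of 999 permutations.
Calibration is part of the test suite: at alpha = 0.05 the empirical type-I
error over 500 null data sets (199 permutations each) must fall in
[0.03, 0.07].

## Classification

**HDRDA.** The regularized class covariance is
`S_k(lambda, gamma) = (1 - lambda) S_k + lambda S_pool + gamma I`, with the
per-class estimate using divisor `n_k - 1` and the pooled estimate divisor
`n - g`. These divisors make the limiting cases exactly pooled-covariance LDA
(`lambda = 1, gamma = 0`) and QDA (`lambda = 0, gamma = 0`), which the tests
verify against independent implementations. Discriminant scores are
`d_k(x) = (x - mu_k)' S_k^{-1} (x - mu_k) + log|S_k| - 2 log pi_k` and
posteriors are `exp(-d_k/2)` normalized per subject, with naive (sample
proportion) priors by default.

When features outnumber subjects, all quantities are computed exactly in the
orthonormal basis of the span of the centred training data (rank
`r <= n - 1`). A test vector's component orthogonal to that span contributes
`||x_perp||^2 / gamma` to every class score, and the log-determinants differ
across classes only inside the span, so the per-subject constant cancels in
the posterior normalization — the reduced computation equals the dense p x p
computation, which the tests check at p = 195, n = 60 to 1e-6.

`gamma` is expressed by default in units of the mean pooled variance
(`trace/p`), because Procrustes shape coordinates have variances around 1e-5
and an absolute ridge would otherwise need rescaling per data set; an
absolute mode is available for oracle comparisons. The default tuning grid is
`lambda in {0, .25, .5, .75, 1}` by `gamma in {1e-4, ..., 1}` (relative), with
ties broken toward heavier regularization. Whether to tune once globally or
per fold is exposed as a choice for the user; tuning once globally is the
default workflow.

**CVA.** Shapes are projected onto principal components retaining 99% of
variance (capped at `n - g` so the within-group covariance stays
nonsingular); canonical axes solve the between/within generalized
eigenproblem; scores are scaled so the pooled within-group covariance of
canonical scores is the identity; classification is by Euclidean (=
Mahalanobis) distance to centroids in canonical space with prior adjustment.
CVA degrades when per-class n falls below the retained dimensionality, which
is the qualitative reason the regularized classifier is preferred for rare
syndromes.

**Cross-validation.** Family-level leave-one-out holds out one family at a
time, never splitting a family between training and test; subjects without a
family form singleton families, so the scheme reduces to ordinary LOOCV on
unrelated cohorts. Stratified 20-fold CV is provided for comparison; k-fold
can underestimate sensitivity for very small classes. Relatives are excluded
from every training set and from the reports. If a fold's training set loses
an entire class, that class's posterior is 0 in that fold and a warning is
logged. Minimum syndrome size defaults to n >= 10, and the reserved
`"unaffected"` label is always retained by the filter.

## Syndrome shape-space statistics

- *Severity*: mean shape distance of a syndrome's subjects to the
  unrelated-unaffected mean.
- *Distinctiveness*: distance from the syndrome mean to the nearest other
  syndrome mean (unaffected excluded as a neighbour).
- *Within-syndrome variance*: mean squared distance to the syndrome's own
  mean (= trace of the within-class coordinate covariance).
- *Integratedness*: relative eigenvalue variance of the within-class
  covariance, `Var(lambda) / (mean(lambda)^2 (m - 1))` over the nonzero
  eigenvalues (above 1e-12 of the largest, since landmark covariances are
  rank-deficient); 0 for spherical variation, 1 for rank-1 variation.
- *Covariance distance*: the affine-invariant Riemannian metric
  `||log(A^{-1/2} B A^{-1/2})||_F` on ridge-regularized covariances, with
  log-Euclidean as an alternative. No canonical metric exists for this
  quantity; the affine-invariant one was chosen for its metric properties.
  The reference covariance defaults to the unaffected class (pooled is a
  switch). Sample covariances here have rank at most n - 1, so the default
  ridge is a non-negligible 1e-3 of the mean variance.

`determinants_analysis()` regresses per-syndrome sensitivity on severity,
distinctiveness, within-variance, integratedness and log n (simple and
combined models), extracts PC1 of the standardized determinant matrix, and
regresses the between-method sensitivity difference on PC1.

## Unaffected relatives

For each family with at least one relative, the classifier is refitted
leaving out that family's syndromic members; relatives never appear in any
training set. Per relative we record the predicted class, whether the family
syndrome ranks in the top 10 posteriors, and phenotypic extremeness (distance
to the unaffected mean). Cohort-level tests: Brown–Forsythe Levene test
(median-centred; classic mean-centring by flag) of extremeness across family
syndromes; OLS regression of extremeness on family-syndrome severity
(reporting model MS and F); Pearson chi-square without continuity correction
comparing the classified-unaffected fraction of relatives against unrelated
unaffecteds, the latter taken from the same cross-validated report as the
main analysis rather than refit.

## The synthetic cohort generator

No raw facial scans ship with the package (the study data behind this kind of
analysis is controlled-access), so `generate_cohort()` draws cohorts with the
statistical structure the analysis assumes and records all latent values:

- a bilaterally symmetric face-like template (65 landmarks = 30 pairs + 5
  midline by default) with points on the front of an ellipsoid;
- per-syndrome mean offsets `s_k u_k` along unit directions in the symmetric
  shape subspace — mutually orthogonal, or clustered at a configurable angle;
  per-class severities are `severity_scale` times multipliers evenly spaced
  in [0.5, 1.5], because a flat severity profile would make severity-recovery
  rank correlations undefined;
- Gaussian within-class deviations in the symmetric subspace, spherical or
  with geometrically decaying eigenvalues (`rho` tunes integratedness), RMS
  magnitude `within_sigma`, optionally scaled by `1 + c s_k`
  (severity–variance coupling, `c = 10`);
- a fixed cubic growth trajectory and an additive sex contrast along their
  own symmetric unit directions; antisymmetric noise of RMS
  `asymmetry_noise`;
- family structure: each family shares a Gaussian shape effect, and its
  "unaffected" relative carries `a` times the family syndrome's mean offset
  (`a = 0` reproduces unaffected draws, `a = 1` full syndromic expression);
- a random rigid motion and log-uniform scale in [0.8, 1.25] per subject so
  superimposition is genuinely exercised.

Default magnitudes (severity 0.02, within 0.05, growth 0.05, sex 0.015,
asymmetry 0.01 Procrustes units, ages 1–70) were fixed once to mimic a cohort
in which age is a major, sex a minor, and syndrome an intermediate source of
variance. All randomness derives from one seed, split into fixed streams for
the template, the latent structure, the subject draws and the rigid motions,
so stages regenerate independently.

What the generator does *not* emulate: non-Gaussian within-syndrome
variation, measurement error correlated along the facial surface, age- or
sex-by-syndrome interactions, camera effects, and race/ethnicity structure.
Tests passing on these cohorts therefore validate the statistical machinery,
not clinical performance on real faces.

## Numerical and design choices

- Landmark indices are 1-based everywhere (R convention), including the file
  dialects.
- Coordinates are kept in the file's units; GPA removes scale.
- The reflection plane for symmetrization is the first coordinate axis of the
  aligned frame; cohorts must be roughly mid-sagittally oriented, which
  consensus alignment of face-like templates provides.
- Tangent-space projection is the identity on aligned coordinates; at the
  Procrustes distances of facial data the orthogonal projection differs
  negligibly.
- Top-k ties are broken by class label order for determinism.
- Test problem sizes: cohorts of 30 landmarks and 150–500 subjects, 8–30
  syndromes; calibration suites use 500 replicates at 199 permutations.
  Severity-recovery assertions use `severity_scale = 0.05`, where adjacent
  true severities are several standard errors apart at n = 50 — at the
  default 0.02 spacing the estimator cannot rank 8 classes reliably and the
  assertion would be noise.
- The analysis sequence of `run_pipeline()` (GPA, outliers, symmetrization,
  standardization, MANOVA, min-n filter, two-group CVA, multi-class HDRDA and
  CVA with and without the unaffected class, shape-space statistics,
  determinants, relatives) writes every table as CSV plus the resolved
  configuration, and reruns with the same seed are byte-identical.

## Worked example

```{r example, eval = FALSE}
synth <- generate_cohort(generator_config(
  n_syndromes = 8, n_per_syndrome = 25, n_unaffected = 150,
  n_families = 40, severity_scale = 0.05, seed = 1))
prep <- prepare_shapes(synth$cohort)
cv <- crossvalidate(prep$shapes, prep$meta, method = "hdrda",
                    params = hdrda_params(lambda = 1, gamma = 1e-2),
                    scheme = "family")
glance(cv)
tidy(cv)
autoplot(cv)
```

## Limitations

Dense-mesh processing (atlas construction, non-rigid registration to scans)
is out of scope: inputs are landmark configurations. The package computes
statistics, not clinical decisions; posterior calibration beyond the Gaussian
model, race/ethnicity adjustment, and longitudinal modelling are not
implemented.
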