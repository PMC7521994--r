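# morphodx

Geometric-morphometric analysis of 3D facial landmark data for syndrome
diagnosis. Clinicians and morphometricians studying facial dysmorphology work
with cohorts of landmark configurations (k homologous 3D points per face),
subject metadata (age, sex, diagnosis, family), and the question: *can the
syndrome be read off the face, and what makes a syndrome classifiable?*
morphodx implements that full analysis as composable, tested R functions.

## What it computes

Starting from TPS (LM3) or wide-CSV landmark files and a metadata table:

1. **Generalized Procrustes analysis** — remove translation, scale and
   rotation; shapes live in the tangent space at the consensus.
2. **Object-symmetry decomposition** — split each face into symmetric and
   asymmetric components (`x_sym = (x + reflect(x))/2`); classification
   defaults to the symmetric part.
3. **Outlier screening** — robust z-scores of the Procrustes distance to the
   mean and the per-landmark deviation variance, plus a threshold sweep
   against classification accuracy.
4. **Age/sex standardization** — residuals of a multivariate regression of
   shape on an orthogonal cubic age polynomial and a sex contrast.
5. **Procrustes MANOVA** — sequential sums of squares averaged over all term
   orderings, Goodall F statistics, residual-randomization permutation
   p-values.
6. **Classification** — high-dimensional regularized discriminant analysis
   with covariance `(1 − λ)S_k + λS_pooled + γI` (exact when p ≫ n, via the
   span of the centred training data) and canonical variates analysis on a
   PCA-reduced space; naive priors, posteriors per class, top-1/3/10 hits,
   per-class sensitivity/specificity/balanced accuracy; family-level LOOCV
   (never splitting a family) and stratified k-fold.
7. **Syndrome shape-space statistics** — phenotypic severity,
   distinctiveness, within-syndrome variance, integratedness (relative
   eigenvalue variance), covariance distance (affine-invariant Riemannian),
   and regressions of sensitivity on these determinants with PC1 scores.
8. **Unaffected relatives** — classify each relative with a model refitted
   without that family's syndromic members; test whether relatives classify
   as unaffected less often than unrelated unaffecteds (chi-square), whether
   extremeness varies by syndrome (Brown–Forsythe Levene) and tracks the
   family syndrome's severity (OLS, model MS and F).
9. **Synthetic cohorts** — a seeded generator of bilaterally symmetric
   landmark cohorts with controllable severity, class geometry, covariance
   structure, growth/sex effects, families and attenuated relatives, so the
   whole pipeline is testable without any controlled-access data.

Results are tibbles with `tidy()`/`glance()`/`autoplot()` methods and
pipe-friendly signatures; `run_pipeline()` executes the whole sequence and
writes every table as CSV.

## Worked example

```r
library(morphodx)

synth <- generate_cohort(generator_config(
  n_syndromes = 8, n_per_syndrome = 25, n_unaffected = 150,
  n_families = 40, severity_scale = 0.05, seed = 1))
synth$cohort
#> <cohort> 390 subjects, 65 landmarks, 8 syndromes, 40 relatives

prep <- prepare_shapes(synth$cohort)   # GPA, symmetrize, age/sex standardize
cv <- crossvalidate(prep$shapes, prep$meta, method = "hdrda",
                    params = hdrda_params(lambda = 1, gamma = 1e-2),
                    scheme = "family")
cv
#> <classification_report> 350 subjects, 9 classes; mean sensitivity 98.4%,
#>   mean balanced accuracy 99.1%

syndrome_stats(prep$shapes, prep$meta, min_n = 10)
#> # A tibble: 8 × 7
#>   syndrome        n severity distinctiveness within_variance integratedness
#> 1 syndrome_01    25   0.0549          0.0396         0.00240        0.00928
#> 2 syndrome_02    25   0.0585          0.0396         0.00242        0.0118
#> 3 syndrome_03    25   0.0623          0.0471         0.00243        0.0110
#> # … 5 more rows, 1 more variable: covariance_distance
```

At these settings the 350 core subjects are classified with 98.4% mean
sensitivity: the planted mean offsets (0.025–0.075 Procrustes units across
the 8 classes) are large relative to the within-class noise, so the cohort is
nearly separable — lower `severity_scale` to make the task hard. The
severity column recovers the planted ranking (syndrome_01 lowest), and
distinctiveness reflects the orthogonal class geometry.

## Files

- `R/` — implementation; `tests/testthat/` — unit, property and acceptance
  suites; `scripts/acceptance.R` — the reproduction script;
  `vignettes/facial-shape-classification.Rmd` — the methods vignette;
  `inst/scripts/morphodx.R` — a thin command-line wrapper over
  `run_pipeline()`.
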