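---
title: "Covariate importance mapping for voxel-wise lesion-symptom mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate importance mapping for voxel-wise lesion-symptom mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covima)
```

## The model

Voxel-wise lesion-symptom mapping (VLSM) asks, voxel by voxel, whether
patients lesioned at that location have worse clinical outcomes than
patients spared there. covima fits, at every voxel $i$ with sufficient
lesion overlap, the general linear model

$$ S_n = \beta_{i,0} + \beta_{i,1} L_{i,n} + \beta_{i,2}\,\mathrm{age}_n +
   \beta_{i,3}\,\mathrm{vol}_n + \beta_{i,4}\,\mathrm{fup}_n +
   \varepsilon_{i,n}, $$

where $S_n$ is subject $n$'s outcome (an NIHSS-like severity score),
$L_{i,n}$ the binary lesion indicator at voxel $i$, and age (years), lesion
volume (cm³) and follow-up imaging time (hours) are clinical covariates.
The lesion-term t-score $t_i = \hat\beta_{i,1}/\mathrm{SE}(\hat\beta_{i,1})$
is the *eloquence* of the voxel: high positive values mean a lesion there
predicts worse outcome after covariate adjustment.

An intercept is included by default even though the bare regression could
omit it: without an intercept the covariates absorb the outcome's mean
level and standardized coefficients lose their meaning. It can be removed
via `design_spec(intercept = FALSE)`. Covariates enter the fit in their
natural units; standardization happens only at the importance-map stage.
Optional interaction columns (age × volume, volume × follow-up) are
available but off by default, since the marginal model is the primary
object of interest and interactions complicate interpretation.

Because the design matrix is identical at every voxel except the lesion
column, the engine QR-factorizes the shared covariate block once,
residualizes all lesion columns against it, and recovers each voxel's exact
OLS solution by the Frisch–Waugh–Lovell theorem. Results agree with
voxel-by-voxel refits to numerical precision (tested at 1e-8 and below);
the speedup is what makes permutation testing cheap.

### Testability and degenerate designs

A voxel enters the analysis only if at least `min_lesion_count` subjects
are lesioned there and at least `min_nonlesion_count` are spared (5/5 by
default, the common VLSM convention). A voxel whose lesion column is
collinear with the covariate block (squared residual norm below
$10^{-10} n$ after projection) cannot identify a lesion effect and is
dropped from the testable mask with a logged count.

## Family-wise error control

With thousands of voxels tested, covima controls the family-wise error
rate by max-statistic permutation: the outcome vector is permuted across
subjects `n_permutations` times (1000 by default), all testable voxels are
refit per permutation, and the maximum lesion t is recorded. The threshold
is the $\lceil (1-\alpha) B \rceil$-th order statistic of the $B$ max-t
draws ($\alpha = 0.05$ by default) — the conservative quantile convention,
which guarantees marginal FWER $\le \alpha$. Only voxels at or above the
threshold "survive" and enter the importance analysis.

Design choices worth knowing:

* **Permutation scheme.** Only the outcome is permuted; lesions and
  covariates stay fixed. This tests the strong null that the outcome is
  independent of lesions and covariates jointly. It is the scheme of the
  classical VLSM max-statistic correction and is adequate for thresholding
  the lesion term, but it is not a Freedman–Lane residual permutation; with
  strong covariate effects the null distribution is conservative for the
  lesion term specifically. This is a documented limitation.
* **Seeding.** One integer seed expands deterministically into the whole
  permutation sequence, and the sequence is applied in canonical
  (sorted-subject-ID) order, so jointly reordering all inputs cannot change
  the threshold.
* **Observed statistic.** The observed max t is *not* added to the null
  sample by default (pure thresholding); `add_observed = TRUE` gives the
  +1 convention needed for exact p-values.
* **Exhaustive mode.** For $n \le 8$ subjects all $n!$ permutations can be
  enumerated (`exhaustive = TRUE`), which the test suite uses to check the
  sampled path against an exact brute-force oracle.

The suite validates FWER control empirically: over 200 null-simulated
cohorts (100 subjects, ~500 testable voxels, 200 permutations each) the
fraction of cohorts with any surviving voxel must not exceed
$0.05 + 3\sqrt{0.05 \cdot 0.95 / 200} \approx 0.096$. The same study is
recomputed by `scripts/acceptance.R`.

## Covariate importance maps

At each surviving voxel the covariate coefficients are standardized as

$$ \beta s_{i,j} = \hat\beta_{i,j} \sqrt{\frac{\mathrm{var}(x_j)}{\mathrm{MSE}_i}}, $$

i.e. normalized by the covariate's sample variance and the voxel's residual
mean squared error. This makes coefficients of covariates measured in
different units comparable at a voxel, and is invariant to positive
rescaling of any covariate (tested to 1e-8). The fully classical
standardization $\hat\beta_{i,j}\,\mathrm{sd}(x_j)/\mathrm{sd}(S)$ is
available via `convention = "classical"`; the convention used is recorded
in the output metadata.

Each covariate's map is then min–max normalized to $[0, 1]$ over the
surviving voxels. Normalization uses $|\beta s|$ — importance is a
magnitude concept — and the signed raw maps are always emitted alongside,
so no information is lost. A degenerate map (all values equal) normalizes
to all zeros with a warning rather than dividing by zero. Voxels with
$\mathrm{MSE}_i = 0$ (a perfect fit, under which the standardization is
undefined) are excluded with a logged count.

## Regional aggregation and clustering

Normalized importance is averaged over each atlas region's intersection
with the surviving mask. Regions with small overlaps would enter the
clustering as noise, so regions are filtered by overlap voxel count —
either an absolute threshold or a percentile of the overlap distribution
across regions (default: the 50th percentile, computed with linear
interpolation between order statistics). Absolute-mode filtering is
idempotent.

The retained region × covariate matrix is clustered agglomeratively
(Euclidean distance, average linkage by default; complete, single and
Ward linkage are available) via `stats::hclust`, and each region is
labelled with its *dominant* covariate — the argmax of its mean normalized
importance, with ties broken by the fixed covariate order (age, volume,
follow-up) and flagged. `autoplot()` methods draw the importance heatmap in
dendrogram leaf order and the dendrogram itself.

## The synthetic cohort generator

Because clinical lesion cohorts cannot be redistributed, covima ships a
simulator that emulates an MCA-stroke cohort well enough to exercise every
pipeline stage with known ground truth:

* **Grid**: 24³ voxels at 3 mm by default, with lesions confined to an
  interior "territory" box standing in for a vascular territory.
* **Lesions**: single 6-connected blobs grown from a uniformly drawn seed
  voxel by random frontier growth; target sizes are log-normal
  (heavy-tailed, like real infarct volumes), by default with median ≈ 1400
  voxels ≈ 39 cm³ — the tens-of-cm³ scale of MCA infarcts.
* **Covariates**: age ~ Normal(68.6, 12.6²) years truncated at zero by
  resampling; follow-up time ~ Uniform(18, 168) hours (the 18 h – 7 d
  follow-up imaging window of acute stroke studies); lesion volume computed
  from the realized mask. Covariates are mutually independent by
  construction.
* **Outcome**: $S_n = \sum_r f_{r,n}(\gamma_r + \sum_j m_{r,j} z_{j,n}) +
  \sum_j b_j x_{j,n} + \varepsilon_n$, where $f_{r,n}$ is the fraction of
  eloquent region $r$ lesioned in subject $n$ (partial hits give partial
  deficits), $\gamma_r$ the region's effect for a full hit, $m_{r,j}$ an
  optional per-region covariate modulation applied to the
  population-standardized covariate $z_j$, $b_j$ global covariate effects,
  and Gaussian noise (default SD 4 outcome points). Default global effects
  (0.05/yr, 0.08/cm³, 0.01/h) keep the covariates' contribution at a few
  NIHSS points, comparable to their epidemiological effect sizes.
* **Determinism**: one seed drives everything; per-subject lesion growth
  uses deterministically derived sub-streams, so the same spec is
  bit-reproducible.

`null_cohort()` zeroes every regional effect, giving outcomes independent
of lesion location — the null for the FWER study.

What the simulator does *not* model: registration error, imaging
artifacts, multi-lesion patterns, hemispheric asymmetries of the outcome
scale, or any dependence of lesion placement on the covariates. Passing
tests therefore demonstrate the statistical machinery's correctness and
calibration, not that real cohorts behave like the generator.

## What parameter recovery can and cannot mean here

One analytic point shaped the recovery test bed and deserves recording.
In the generative family above, with covariates independent of lesion
placement, the population value of a covariate coefficient
$\beta_{i,j}$ is *identical at every voxel*: all cross-moments that could
make it voxel-specific vanish (for any modulation term
$f_r \cdot z_j$ with $z_j$ centred and independent of the lesions,
$\mathrm{cov}(L_i, f_r z_j) = 0$). Regional structure in the importance
maps therefore comes from the MSE surface — covariate importance is
genuinely higher where lesions explain outcome variance — not from
regionally varying coefficients. A corollary is that min–max-normalized
maps of two covariates that both carry any global effect have the *same*
expected shape, so no test can distinguish them regionally at high SNR.

The recovery scenario is designed around this identifiability constraint:
each simulated cohort has one compact eloquent region whose effect is
modulated by exactly one covariate, all other covariate effects zero, and
a narrow lesion-size distribution (log-SD 0.08) so that lesion volume does
not proxy for region hit fraction. Under those conditions the modulated
covariate's normalized importance peaks in the region while the other
covariates' maps are structureless noise, and `dominant_covariate()`
recovers the ground-truth assignment in well over 90% of simulations
(100 cohorts of 250 subjects; the suite evaluates the region means over
the full testable mask, FWER thresholding being validated separately).
In real data, regionally specific covariate importance additionally draws
on dependence between covariates and lesion anatomy (e.g. age-related
vulnerability of particular territories), which the independence-by-design
simulator deliberately excludes.

## Numerical conventions and edge cases

* Grids match when shapes are equal and affines agree element-wise within
  1e-4 (registered cohorts carry float jitter in their headers).
* Mask binarization: any nonzero voxel is lesion.
* Statistic maps are written float32 with background 0 and a companion
  binary mask volume; 0 is a valid statistic value, so the mask, not the
  fill, defines validity.
* Outcome values outside the integer NIHSS 0–42 range warn but are kept —
  other outcome scales are legitimate.
* VIF is computed from the covariate design alone (the auxiliary
  regressions do not involve the outcome); perfect collinearity reports an
  infinite VIF and a blocking flag rather than an exception. Default flag
  thresholds mirror common screening practice: |r_s| ≥ 0.1 informational,
  VIF ≥ 5 blocking (overridable with `force = TRUE` in the pipeline).
* Spearman correlations use average ranks for ties.
* Percentiles use linear interpolation between order statistics
  (`quantile` type 7).

## Problem sizes used by the test suite

The shipped tests run the FWER study at 200 cohorts × 200 permutations
(~500 testable voxels, 100 subjects), the recovery study at 100 cohorts of
250 subjects on a 12×12×6 grid, and the oracle comparisons on grids of
100–200 voxels with 24–45 subjects. These sizes were chosen so the whole
suite completes in a few minutes on a single core while keeping every
Monte-Carlo bound at 3 standard errors or better.

## A worked example

```{r example, eval = FALSE}
spec <- simulation_spec(grid = voxel_grid(c(12, 12, 6)), n_subjects = 120,
                        size_meanlog = log(40), seed = 7)
sim <- simulate_cohort(spec)

check_collinearity(sim$covariates)

fit <- fit_voxelwise_glm(sim$cohort, sim$covariates)
perm <- permutation_max_t(sim$cohort, sim$covariates,
                          n_permutations = 1000, seed = 8)
map <- apply_threshold(lesion_t_map(fit), perm)
imp <- standardized_betas(fit, map)

# with an atlas parcellation:
# reg <- regional_means(imp, parc) |> overlap_filter() |> dominant_covariate()
# autoplot(reg, clustering = cluster_regions(reg))
```

## Known limitations

* The mass-univariate model ignores correlated lesion anatomy (the partial
  injury problem); multivariate lesion-symptom models are out of scope.
* Outcome-only permutation is conservative for the lesion term when
  covariate effects are strong.
* No robust or regularized regression, spatial smoothing, or mixed models.
* The simulator's realism is explicitly not a claim; it is a test bed with
  known ground truth.
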