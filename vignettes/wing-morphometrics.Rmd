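---
title: "Geometric wing morphometrics with wingmorph: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric wing morphometrics with wingmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`wingmorph` analyses 2D landmark configurations of insect wings — here, 18
wing-vein crossing points per mosquito wing — to compare size and shape
between groups and to assign specimens to species. This vignette explains the
statistical machinery, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the design decisions
taken where conventions differ between tools.

## The data model

A dataset is a tibble with one row per digitized configuration: metadata
(`specimen_id`, `species`, `sex`, `observer`, `site`, `replicate`) followed
by interleaved coordinate columns `x1, y1, ..., xk, yk` (k = 18 throughout
the package's own study design, but any homogeneous k ≥ 3 works). The triple
(`specimen_id`, `observer`, `replicate`) must be unique; `validate_landmarks()`
reports violations, coincident landmarks, non-finite coordinates and mixed
chirality. Coordinates are stored exactly as digitized — no y-axis flip is
applied. Because the superimposition deliberately excludes reflections (all
wings must be the same side, digitized with one handedness), a record whose
landmark-order polygon has the opposite orientation from the rest of the
dataset is flagged as a probable reflected wing rather than silently
absorbed.

Missing landmarks are not supported: a record with fewer than k points is an
error, not an imputation target. TPS input applies `SCALE=` multiplicatively
and takes ids from `ID=` (falling back to the `IMAGE=` basename, then a
running index); TPS output carries coordinates and ids only, so the CSV
dialect is the round-trip-complete format.

## Superimposition

`gpa()` performs generalized Procrustes analysis:

1. centre each configuration and record its centroid size
   CS = sqrt(Σᵢ ‖xᵢ − x̄‖²);
2. scale each to unit centroid size (full Procrustes superimposition — size
   enters all downstream analyses only through CS, never through residual
   scale);
3. initialize the consensus as the first configuration;
4. rotate every configuration onto the consensus by the proper rotation
   (det R = +1, via SVD of the 2×2 cross-covariance with determinant sign
   correction);
5. recompute the consensus as the coordinate-wise mean, re-centred and
   rescaled to unit centroid size;
6. iterate 4–5 until the decrease in the total deviation
   Q = Σ ‖xᵢ − x̄‖² falls below `tol` (default 1e-10, far below any
   biological signal; `max_iter` 100; non-convergence is a recorded warning,
   not an error).

Q is evaluated against the unscaled mean, which makes the trace provably
non-increasing: each rotation step maximizes the projection of every
configuration onto the direction of the previous mean. Two further choices
make the output a deterministic function of the input:

* **Orientation gauge.** GPA output is defined only up to a common rotation.
  The final consensus (and all configurations with it) is rigidly rotated to
  best match the first specimen's original orientation, giving byte-stable
  coordinates and reproducible PCA signs.
* **Reflections excluded.** A reflection would silently mask a digitization
  chirality error, so it is treated as a data problem (see above), never as a
  transform for the optimizer to absorb.

With `project = TRUE` (default) the aligned shapes are orthogonally projected
onto the tangent space at the consensus, v' = v_c + (I − v_c v_cᵀ)(v − v_c)
with v_c the flattened unit-norm consensus, so that the downstream linear
models (regression, PCA, LDA) operate in a flat space. At the shape variances
typical of conspecific wings (Procrustes variance ~1e-3) the projection moves
coordinates by a numerically negligible amount — the test suite quantifies
this rather than assuming it — but the flag is exposed because conventions
differ between toolchains.

## Inferential statistics

All permutation tests share one convention: the predictor (group labels or
the size covariate) is fully randomized — equivalent, for these single-factor
designs, to residual randomization under the intercept-only reduced model;
the observed statistic is counted among the permutations, so
p = (c + 1)/(N + 1) and p ≥ 1/(N + 1); and the standardized effect size is
Z = (F_obs − mean F_perm)/sd F_perm on the untransformed F. Permutation
results are bit-reproducible under a fixed RNG seed.

* `size_anova()` — classical one-way ANOVA of centroid size on a factor,
  with the parametric F-distribution p-value always reported and a
  permutation p-value on request. The study design this package emulates
  uses the parametric test for the species contrast and 500 permutations for
  the observer contrast.
* `allometry_regression()` — the Procrustes linear model shape ~ size: every
  superimposed coordinate is regressed on CS, sums of squares are totalled
  across coordinates (they are then sums of squared Procrustes deviations),
  and R² = SS_model/SS_total, F = (SS_model/1)/(SS_resid/(n − 2)). Default
  1000 permutations. The covariate is raw CS to match the most common
  default; `log_size = TRUE` is available because the choice is a genuine
  convention split and the difference matters only for strongly size-ranged
  samples.
* `morphological_disparity()` — per-group Procrustes variance
  PV_g = (1/n_g) Σᵢ ‖vᵢ − v̄_g‖², i.e. the *mean* squared deviation
  (denominator n, not n − 1 — users comparing against n − 1 conventions
  should multiply by n/(n − 1)); pairwise |PV differences| with optional
  label-permutation p-values.
* `observer_repeatability()` — within-specimen PV (mean over replicated
  specimens of the PV of that specimen's digitizations) against
  within-species PV computed on one measurement per specimen. Digitization
  noise well below biological variation indicates low observer bias. With r
  replicates and denominator n, the expected within-specimen PV under
  isotropic noise σ is (2k − 4)σ²(r − 1)/r — the finite-replicate factor
  matters at r = 3 and is used wherever the package checks itself.
* The observer size ANOVA is a plain one-way ANOVA on the observer factor.
  Whether specimen identity should enter as a blocking factor is a genuine
  open question in replicated-digitization designs; the plain model is used
  here, and its permutation null is exact only under exchangeability (the
  calibration tests construct exchangeable nulls for this reason).

Why (2k − 4)? Isotropic landmark noise has 2k coordinate degrees of freedom,
of which 2D superimposition absorbs four: two translation, one rotation, one
scale. This identity (verified by simulation in the test suite) is what makes
the generator's noise parameters directly comparable to the Procrustes
variances the pipeline estimates.

## Classification

`shape_pca()` is an eigendecomposition of the covariance of the shape
vectors, retaining components with eigenvalue > 1e-12 × the largest
(superimposition leaves at most 2k − 4 non-null dimensions) and fixing each
loading's sign so its largest-magnitude element is positive.

`lda_fit()` is the two-class linear discriminant from the pooled
within-class covariance W (divisor n − 2): w = W⁻¹(μ₁ − μ₂), decision score
x·w − w·(μ₁ + μ₂)/2 + ln(p₁/p₂), posterior from the equal-covariance
two-Gaussian model. Priors default to class frequencies (`"equal"` by
option). Scores of exactly zero are assigned to the first level
deterministically and counted.

`loocv_classify()` holds out each specimen in turn. Three deliberate choices:

* **Feature space.** Raw superimposed coordinates are rank-deficient, so W
  would be singular; the LDA runs on full-rank PCA scores, which is an
  orthogonal rotation and therefore loses no information relative to any
  generalized-inverse treatment. The component count is capped at
  min(n − 3, 2k − 4): inside a fold the pooled covariance has rank n − 3,
  one less than the full-sample bound.
* **Basis computed once.** The superimposition and PCA basis come from the
  full sample, not per fold — matching how built-in cross-validation in
  standard LDA implementations operates on precomputed shape coordinates.
  This is mildly optimistic; `refit_basis = TRUE` gives the strict per-fold
  variant.
* **Accuracy contract.** Reported accuracy is exactly
  trace(confusion)/n (`accuracy_from_confusion()`), so published confusion
  counts can be checked independently of any model run.

`landmark_differences()` ranks landmarks by the magnitude of the displacement
between group mean shapes and can attach a per-landmark two-feature LOOCV
accuracy, quantifying the standard observation that no single landmark
suffices for identification.

## The synthetic study generator

The deposited raw data for studies of this kind are wing *images*; landmark
coordinates exist only after manual digitization. The generator therefore
stands in for the real data with a forward model of everything the analysis
assumes, so that each pipeline stage has a ground truth. A specimen's latent
shape is

> s = template ± a/2 ± b/2 + β (log CS − mean log CS) u + ε,

where `template` is a fixed wing-like 18-point configuration (unit centroid
size; an elongated outline with interior fork points; the constants are
documented generator values, not measurements), `a` and `b` are fixed unit
displacement fields for species and sex scaled to Procrustes magnitudes
`species_d` and `sex_d`, `u` is a fixed unit allometry direction, and ε is
i.i.d. N(0, σ_ind²) per coordinate. Raw coordinates are CS·R(θ)·s + t with
θ ~ U(0, 2π) and t uniform in a box. Noise and effect fields live in shape
space *before* the nuisance transform and are projected into the tangent
space at the template (their translation/rotation/scale components removed),
so that generator magnitudes survive superimposition essentially unchanged
and compare directly to estimated Procrustes variances and mean-shape
distances. Replicated digitizations add N(0, σ_obs²) shape noise to the
specimen's latent shape and reuse its CS, θ and t — the same mounted image
re-clicked by another observer; an optional constant per-observer offset
(`observer_bias`) simulates a biased digitizer, off by default.

Defaults (one documented table, chosen once):

| parameter | default | meaning / rationale |
|---|---|---|
| `group_sizes` | 77 / 70 / 67 / 57 | the emulated study's females/males per species (271 wings) |
| `species_d` | 0.02 | Procrustes distance between species mean shapes; yields classification accuracy of the observed order |
| `species_focus_share` | 0.5 at landmark 18 | half the displacement norm at the medial fork, the landmark reported most informative; remainder spread over landmarks 1–17 |
| `sex_d` | 0.04 | sexual shape dimorphism, stronger than the species signal — the reason sexes are never pooled |
| `cs_base`, `cs_sdlog` | 3.0, 0.06 | lognormal centroid size in arbitrary image units (no physical calibration is assumed) with a realistic ~6% size CV |
| `cs_female_koreicus_factor` | 1.02 | small female size advantage of *Ae. koreicus*; male means equal |
| `cs_male_factor` | 0.90 | males smaller than females |
| `allometry_beta` | 0.13 | shape displacement per unit log CS; with cs_sdlog = 0.06 gives shape-on-size R² ≈ 0.03, the weak allometry regime reported for conspecific wings |
| `sigma_ind` | 0.0068 | individual shape noise; within-group PV ≈ (2k − 4)σ² ≈ 1.5e-3, matching published within-species Procrustes variances (0.9–1.7e-3) |
| `sigma_obs` | 0.0043 | digitization noise; within-specimen PV ≈ (2k − 4)σ²·2/3 ≈ 3.9e-4 for three observers, matching published repeatability values (3.4–4.4e-4) |
| `n_observers`, `n_replicated` | 3, 20 | three observers re-digitize 20 wings per species × sex (80 wings, 240 replicate records) |

What the generator does **not** emulate — and hence what passing tests do and
do not show about real wings:

* Real wing-shape variation is strongly *correlated* across landmarks
  (integrated venation), concentrating variance on the first few principal
  components; isotropic noise spreads it almost evenly, so the generator's
  PC1+PC2 percentages (~15%) are far below the ~40–50% typical of real
  wings. Tests of PCA therefore validate the decomposition, not the spectrum
  shape.
* Effect fields and noise are homoscedastic across landmarks; real
  digitization error varies with local scale cover and vein visibility.
* No site structure, measurement drift, or size–shape interaction beyond the
  single linear allometric direction.

`recover_parameters()` closes the loop: it runs the full pipeline on a
generated dataset and compares estimated Procrustes variances, mean-shape
distance, allometry R² and the focus-landmark ranking against their analytic
targets, including the (n − 1)/n and (r − 1)/r finite-sample factors and the
allometric inflation of within-group variance.

## Pipeline, reporting, determinism

`run_analysis()` always splits by sex (a `pooled` escape hatch exists and
prints a prominent warning), runs GPA, size ANOVA, allometry, PCA, LOOCV
classification, disparity and per-landmark differences on the replicate-1
records, and the observer analyses (size ANOVA on observer, repeatability,
replicated-set LOOCV) on the replicated records when present. A sex with too
few specimens for classification is skipped for that stage only, with a
warning. Every random element is governed by the single config seed, and the
JSON report is byte-identical across reruns of the same (input, config,
seed); its provenance block carries the seed, a config hash and the package
version (deliberately no wall-clock timestamp, which would break
reproducibility of the artifact). Numbers are serialized at full precision;
display rounding (F to 2 dp, R² to 3 dp, PV to 6 dp) happens only in the
human-readable `print()` summaries.

## Problem sizes in the test suite

The suite validates the heavy properties at reduced, stated sizes chosen as
the package's own test design: permutation-test calibration uses 200
replicate null datasets of n = 60 with 500 permutations each; GPA invariants
run over 100 generated datasets; the accuracy–effect-size curve uses 20
replicates per effect size at n = 60, plus 5 replicates at the full 271-wing
design; the landmark-ranking recovery uses 100 replicates at n = 80. Oracle
checks (rotation-grid alignment, textbook ANOVA, PCA reconstruction,
reference LDA) run at full precision tolerances (1e-6 to 1e-12).

## Known limitations

* Two classes only; no quadratic or regularized discriminants, no >2-group
  disparity frameworks, no multi-factor Procrustes ANOVA or mixed models.
* 2D landmarks only; no semilandmarks, sliding, missing-landmark estimation
  or bilateral-symmetry decomposition.
* Centroid sizes are in digitization units; cross-dataset size comparisons
  assume a shared image calibration, which the package cannot verify.
* The LOOCV shortcut (basis computed once) is the field's convention but is
  mildly optimistic relative to the strict per-fold variant, which is
  provided for sensitivity analysis.
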