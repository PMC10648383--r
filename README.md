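# wingmorph

Landmark-based geometric wing morphometrics for discriminating the invasive
bush mosquitoes *Aedes japonicus japonicus* and *Aedes koreicus*.

The two species are close relatives, occur in sympatry in Europe, and are
hard to tell apart morphologically — yet they may differ in vector capacity,
so surveillance programmes need a cheap, reliable identification tool.
Wing-venation landmarks provide one: the coordinates of 18 vein crosses on a
photographed left wing carry enough shape information to assign species with
accuracy comparable to molecular barcoding. `wingmorph` implements the full
analysis chain for that task, for entomologists and morphometricians working
with 2D landmark data:

* **Landmark I/O** — TPS (tpsDIG conventions: `LM=`, `ID=`, `IMAGE=`,
  `SCALE=`) and a wide CSV dialect with specimen metadata (species, sex,
  observer, site, digitization replicate), plus dataset validation
  (coincident landmarks, duplicate keys, mixed chirality).
* **Generalized Procrustes analysis (GPA)** — iterative least-squares removal
  of translation, scale and rotation; centroid sizes
  CS = sqrt(Σᵢ ‖xᵢ − x̄‖²); consensus shape; optional tangent-space
  projection; deterministic orientation gauge.
* **Morphometric statistics** — centroid-size ANOVA; Procrustes regression of
  shape on size (allometry, F and R² from sums of squares totalled across
  coordinates) with predictor-randomization permutation tests
  (p = (c + 1)/(N + 1), Z = standardized F); morphological disparity
  (Procrustes variance, PV = (1/n) Σᵢ ‖vᵢ − v̄‖²); observer repeatability on
  replicated digitizations.
* **Classification** — shape PCA, two-class linear discriminant
  w = W⁻¹(μ₁ − μ₂) on full-rank PC scores, leave-one-out cross-validated
  species assignment with confusion matrix and accuracy, per-landmark
  mean-shape difference ranking.
* **Synthetic study generator** — a fully parameterized forward model
  (species/sex mean-shape displacement fields, lognormal centroid sizes,
  allometric slope, individual and observer shape noise, replicated
  three-observer design) that reproduces the statistical structure of a real
  two-species wing study, so the whole pipeline is testable without images.
* **Pipeline + CLI** — `run_analysis()` executes every stage per sex
  (mosquito wings are sexually dimorphic; sexes are never pooled by default)
  and writes a deterministic JSON report plus CSV tables;
  `morpho_cli()` / `inst/cli/wingmorph.R` expose `simulate`, `validate`,
  `analyze`, `observer` and `version` subcommands.

Everything is tidyverse-native: datasets are tibbles (one row per digitized
configuration: metadata plus `x1, y1, ..., x18, y18`), every user-facing
function takes the data frame first, and fitted objects have broom-style
`tidy()`/`glance()` methods and ggplot2 `autoplot()` views.

## Worked example

Simulate a study with the default design (77/70 female/male *Ae. j.
japonicus*, 67/57 *Ae. koreicus*, three observers re-digitizing 20 wings per
species and sex) and analyse the females:

```r
library(wingmorph)

spec  <- synthetic_spec()
wings <- generate_study(spec, seed = 1)
females <- subset(wings, sex == "female" & replicate == 1)

sup <- gpa(females)            # Procrustes superimposition
aligned <- tidy(sup)           # tibble: metadata + shape coords + centroid_size

size_anova(aligned, species)
#> size ANOVA (term: species)
#>   F(1, 142) = 2.07, R^2 = 0.014
#>   parametric P = 0.1525

set.seed(1)
allometry_regression(aligned, n_permutations = 1000)
#> Procrustes shape ~ size regression (term: centroid size)
#>   F(1, 142) = 5.06, R^2 = 0.034
#>   permutation P = 0.000999, Z = 15.848 (1000 permutations)

loocv_classify(aligned, species)
#> Leave-one-out cross-validated LDA classification
#>   accuracy: 91.0% (131 / 144)
#>   confusion (rows = true, cols = predicted):
#>                     japonicus   koreicus
#>          japonicus         69          8
#>           koreicus          5         62

landmark_differences(aligned, species)
#> Mean-shape differences: japonicus vs koreicus
#>   #1 landmark 18: |d| = 0.01027
#>   #2 landmark 4: |d| = 0.00634
#>   #3 landmark 15: |d| = 0.00508
```

Reading the output: wing *size* barely separates the species (F(1,142) =
2.07, P = 0.15 here — and even a significant size difference overlaps far too
much for identification), there is a weak but significant allometric
shape–size effect (R² = 0.034), while wing *shape* assigns species with 91%
leave-one-out accuracy. The largest mean-shape difference sits at landmark 18
(the medial fork), but no single landmark separates the species on its own —
exactly the pattern the method is designed to exploit.

The same analysis end-to-end, from the shell:

```sh
Rscript inst/cli/wingmorph.R simulate --seed 42 --out data/
Rscript inst/cli/wingmorph.R analyze --input data/wings.csv --seed 42 --out results/
```

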