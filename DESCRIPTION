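Package: wingmorph
Title: Geometric Wing Morphometrics for Mosquito Species Discrimination
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics of insect wings,
    built for discriminating closely related mosquito species (Aedes
    japonicus japonicus vs. Aedes koreicus) from 18 wing-vein landmarks.
    Provides TPS/CSV landmark input and output with validation,
    generalized Procrustes superimposition with tangent projection,
    centroid-size and allometry permutation tests, Procrustes-variance
    morphological disparity, observer-repeatability analysis, PCA and
    linear discriminant classification with leave-one-out
    cross-validation, a parameterized synthetic wing-landmark study
    generator, and a per-sex analysis pipeline with a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    MASS,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
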