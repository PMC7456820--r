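Package: covima
Title: Covariate Importance Mapping for Voxel-Wise Lesion-Symptom Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise lesion-symptom mapping (VLSM) with covariate
    importance estimation for stroke cohorts. Fits independent per-voxel
    general linear models relating binary lesion status plus clinical
    covariates (age, lesion volume, follow-up imaging time) to an outcome
    score such as the NIHSS, controls the family-wise error rate with
    max-statistic permutation thresholding, converts fitted coefficients
    into standardized-beta covariate importance maps normalized to [0, 1],
    and aggregates importance to atlas regions with overlap filtering and
    hierarchical clustering. Includes a synthetic stroke-cohort simulator
    with known ground truth so the entire pipeline can be validated by
    parameter recovery without patient data, plus collinearity screening
    (Spearman correlation, variance inflation factors) of the covariates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
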