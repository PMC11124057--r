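Package: desolv
Title: Solubility of COX Inhibitors in Deep Eutectic Solvent-Water Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for designing deep eutectic solvent (DES) formulations for
    poorly soluble drugs such as ibuprofen and ketoprofen. Implements a
    simplified COSMO-RS sigma-potential engine on the canonical 61-point
    screening-charge grid, fusion-data-based ideal solubility and full
    solid-liquid equilibrium (SLE) saturation solving, R-squared-filtered
    relative sigma-potential descriptor selection, learning-curve-penalised
    hyperparameter tuning with a tree-structured Parzen estimator, multi-layer
    perceptron regression trained by L-BFGS, validation-RMSD-optimal pruned
    ensembles, and the wet-lab data-reduction steps (UV calibration with
    LOD/LOQ, absorbance to mole-fraction conversion, triplicate aggregation,
    cosolvency-curve analysis). A synthetic-data module generates
    sigma-profiles, solubility surfaces with planted structure, calibration
    series and cosolvency curves so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
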