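Package: torsionflux
Title: Predicting Backbone Torsion-Angle Fluctuations from Protein Sequence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving per-residue backbone torsion-angle fluctuation
    labels (normalized dphi/dpsi) from multi-model structural ensembles such as
    NMR depositions, assembling sliding-window sequence-derived feature
    matrices (residue identity, physicochemical factors, conservation
    profiles, predicted structure and flexibility), selecting features with a
    wrapper genetic algorithm scored by a gradient-boosted tree regressor, and
    training and evaluating fluctuation predictors under chain-level
    cross-validation. Includes a synthetic-ensemble and planted-signal
    simulator so the whole pipeline can be exercised end to end without
    external data, plus a command-line interface for stage-wise runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
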