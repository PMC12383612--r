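Package: maxentSDM
Title: Presence-Background Maximum-Entropy Species Distribution Modeling
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained pipeline for presence-background species
    distribution modeling on latitude/longitude raster grids: grid-based
    spatial thinning of occurrence records, terrain derivation and
    Spearman-based collinearity screening of environmental predictors, a
    from-scratch L1-regularized maximum-entropy (Gibbs) model with
    linear/quadratic/product/hinge/threshold features, ENMeval-style
    tuning over regularization-multiplier and feature-class grids using
    AICc, 10-percentile omission and AUC difference, replicated
    train/test runs, suitability classification with spherical cell
    areas, habitat gain/loss/retention change matrices between climate
    periods, and suitability-weighted centroid migration tracks. Includes
    a synthetic-data generator (autocorrelated random fields, Gibbs
    ground truth, clustered occurrence sampling) so the entire pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    geosphere,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'AllGenerics.R'
    'grid.R'
    'envstack.R'
    'io.R'
    'synthetic.R'
    'occurrences.R'
    'terrain.R'
    'screening.R'
    'features.R'
    'maxent.R'
    'maxent-diagnostics.R'
    'selection.R'
    'habitat.R'
    'rangeshift.R'
    'reported.R'
    'pipeline.R'
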