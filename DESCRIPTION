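Package: darkatlas
Title: Dark Diversity Estimation from Gridded Atlas Data
Version: 0.1.0
Authors@R: person("Atlas", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates dark diversity (ecologically suitable but locally
    absent species) from site-by-species presence/absence matrices on
    regular atlas grids. Implements two complementary estimators: species
    co-occurrence (Beals smoothing with per-species quantile thresholds)
    and species distribution modelling (per-species binomial additive
    models with repeated calibration/evaluation splits and TSS-optimal
    binarization). Provides dispersal (geographic radius) and
    biogeographic (dispersion field) eligibility filters, consensus and
    composite combinations, completeness of site diversity, and
    method-comparison statistics (overlap coefficient, exact
    hypergeometric overlap tests, type II major-axis regression). A
    synthetic-atlas generator with known ground truth supports validation
    of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    mgcv,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
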