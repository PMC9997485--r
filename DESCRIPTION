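Package: relake
Title: Process-Based Simulation of Lake Re-Eutrophication and
    Cyanobacterial Bloom Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale, one-dimensional stratified lake ecosystem
    model for studying re-eutrophication of groundwater-fed lakes after
    phosphorus precipitation. Couples a vertical thermal model
    (hypsographic grid, surface heat budget, parametric eddy diffusivity,
    convective mixing) to a PCLake-style biogeochemistry with three
    phytoplankton groups (buoyant cyanobacteria), two zooplankton groups,
    nitrogen/phosphorus/silicon/oxygen cycling and a sediment pool with
    temperature- and oxygen-dependent diffusive phosphorus release.
    Includes a synthetic meteorological forcing generator with a
    configurable secular warming trend and detrended counterfactual
    variants, linear-regression bias correction, staged parameter
    calibration with correlation/relative-error performance categories,
    a two-by-two climate-warming by internal-loading factorial with
    two-way ANOVA variance attribution, and Mann-Kendall/Sen trend
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lhs,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
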