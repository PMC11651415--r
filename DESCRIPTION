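Package: tpaicrop
Title: Oilseed Rape Growth Simulation and Calibration with the Total
    Photosynthetic Area Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for simulating winter oilseed rape growth
    and yield with a WOFOST-style daily potential-production engine whose
    photosynthetic canopy includes silique (pod) area.  Provides the total
    photosynthetic area index (TPAI = LAI + pod area index), field-formula
    helpers converting organ geometry and plot counts into canopy indices,
    two TPAI-based parameter calibration methods (TPAI-SPA and TPAI-Curve)
    alongside the traditional LAI-only baseline, an extended FAST
    variance-based sensitivity analysis with simplex-constrained dry-matter
    partition coefficients, inverse-distance-weighted weather interpolation,
    accuracy metrics, and seeded synthetic-data generators for weather,
    parameter truths and observation campaigns.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
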