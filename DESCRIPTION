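Package: climspace
Title: Holdridge Life Zones and the Safe Climatic Space of Food Production
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A gridded agro-climatology pipeline around the Holdridge life zone
    (HLZ) system. Classifies monthly-climate rasters into Holdridge life zones
    from annual precipitation, biotemperature (sub-zero months contributing
    zero, no upper cap) and the potential-evapotranspiration ratio; quantifies
    the magnitude and direction of climatic change in Holdridge-triangle
    coordinates, normalized by the spacing between zone centroids; classifies
    change and societal resilience into area-weighted quartile classes and
    cross-tabulates crop and livestock production over the resulting risk
    matrix; and constructs the production-weighted safe climatic space (SCS),
    the region of the triangle holding 95 percent of current production mass,
    to estimate the share of production facing unprecedented climatic
    conditions under future scenarios, per climate model and as an ensemble.
    Includes a seeded synthetic-data generator emulating monthly climate,
    production, resilience and country rasters with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
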