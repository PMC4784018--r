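Package: estselect
Title: Source and Receptor Site Screening for Ecosystem-Scale Translocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible GIS screening pipeline for ecosystem-scale
    translocation (EST) planning. Classifies ecoregions by mean climate
    stability across seven future-climate scenarios, derives candidate source
    areas (climatically unstable land of high conservation value) and receptor
    areas (climatically stable, highly degraded land) by polygon overlay,
    clips them to country boundaries, measures per-country total areas and
    minimum source-receptor distances (planar or geodesic), and ranks
    countries by limiting-factor thresholds. Includes a synthetic vector-world
    generator with analytically known ground truth so every stage is testable
    without external datasets, plus GeoJSON/CSV/YAML input and output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
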