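Package: socdyn
Title: Regional Soil Organic Carbon Dynamics with a Multi-Pool Turnover Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A carbon-only, monthly-timestep, CENTURY-style multi-pool soil
    organic carbon (SOC) turnover model for the 0-20 cm layer of dry farmland,
    together with the machinery needed to run it at regional scale: a
    three-stage spin-up (natural grassland equilibrium, historical low-input
    agriculture, early-fertilizer agriculture) with potential-productivity
    (PRDX) calibration against measured initial SOC, polygon-based regional
    scaling with nearest-station climate assignment, SOC density and stock
    accounting, Nash-Sutcliffe-type model validation statistics, and seeded
    synthetic-data generators emulating a temperate continental monsoon
    cropping region so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
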