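Package: coastveg
Title: Vegetation Cover, Land Surface Temperature and Heat-Island Analysis for Coastal Cities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy raster pipeline for studying how vegetation moderates the
    urban thermal environment in coastal cities. Computes NDVI and inverts
    fractional vegetation cover (FVC) with the dimidiate pixel model, retrieves
    land surface temperature (LST) from a thermal band via the radiative
    transfer equation and the inverse Planck relation, classifies LST into five
    mean-standard-deviation temperature zones and summarises them with the
    urban heat island ratio index (URI), and stratifies the LST~FVC
    relationship by distance to the coastline on a fishnet grid. Ships a
    synthetic coastal-scene generator with known ground truth so the whole
    chain is testable end to end, plus plain-text raster/vector I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
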