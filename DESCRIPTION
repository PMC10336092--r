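Package: fragdyn
Title: Static and Dynamic Forest Fragmentation Analysis on Gridded Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify forest fragmentation and its change from
    bi-temporal binary forest/non-forest rasters. The study extent is tiled
    into square analysis cells ("landscapes"); per cell the class-level
    metrics edge density (ED), patch density (PD), mean patch area (MPA) and
    forest coverage (FC) are computed, normalized with cross-epoch
    comparability, and composed into a forest fragmentation index (FFI) per
    epoch together with its change (dFFI) and the coverage change (dFC).
    Cells are classified into eight fragmentation-process modes from the sign
    triple of the metric changes and into four landscape-dynamic patterns
    from the signs of dFC and dFFI, with zonal and hotspot summaries.
    Standardized multiple linear models attribute dFFI to driver covariates
    and build a coarse-grid major-driver map. A neutral-landscape simulator
    generates bi-temporal scenarios with known change operators and planted
    driver effects so the whole pipeline can be exercised against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
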