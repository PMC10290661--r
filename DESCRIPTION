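Package: nficarbon
Title: Plot-Level Forest Carbon Estimation for National Forest Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for plot-level forest carbon estimation from national
    forest inventory field data, following the design of Nepal's
    forest resource assessment. Implements log-linear allometric stem
    volume and biomass equations with taper-based partial volumes for
    broken trees and stumps, concentric circular sample plot (CCSP)
    expansion to per-hectare aboveground biomass, soil organic carbon
    stocks for 0-30 cm from composite core samples with fine-fraction
    bulk density, Walkley-Black total-carbon correction and coarse
    fragment (stoniness) adjustment, design-based stratified cluster
    summary statistics, and a seeded synthetic inventory generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
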