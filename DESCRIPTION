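Package: deforheat
Title: Deforestation-Induced Local Warming and Heat-Attributable Mortality
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for isolating local deforestation-induced land surface
    warming from gridded temperature-change data by moving-window counterfactual
    matching against nearby elevation-matched forest pixels, and for converting
    that warming into population exposure and annual heat-attributable
    non-accidental mortality via heat vulnerability indices. Includes quality
    screening and compositing of land surface temperature stacks, forest-cover
    change classification, area-weighted and bilinear regridding on regular
    latitude-longitude grids, exposure and mortality aggregation to
    administrative units, and a seeded synthetic-landscape generator with known
    ground truth for end-to-end testing without satellite inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
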