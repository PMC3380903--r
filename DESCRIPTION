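Package: rainindex
Title: Design and Pricing of Rainfall-Deficit Index Insurance for Drought-Prone Crops
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to design site-specific weather-index insurance against
    crop drought. A seeded Markov-chain/gamma daily rainfall generator and a
    soil-bucket water-balance yield model produce multi-year run tables per
    site and soil; per-dekad minimum water requirements (MWRs) are then
    calibrated by constrained optimization so that the total rainfall deficit
    of the lowest yield quartile maximally correlates with simulated yield.
    The calibrated MWR row defines a transparent insurance contract with a
    sowing-date rule, a trigger on the total seasonal deficit and a per-mm
    indemnity; empirical trigger-exceedance probabilities and burn-rate
    premiums are computed across grids of sites and soils.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
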