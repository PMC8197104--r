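Package: comfortrisk
Title: Outdoor Thermal Comfort and Construction Accident Risk Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing construction injuries and fatalities as a
    function of outdoor thermal comfort. Computes Fanger's predicted mean
    vote (PMV) and the physiological equivalent temperature (PET) from
    hourly weather records, links accident registry records to district
    level climate records, classifies events into seasons and PET comfort
    bands, estimates cold/hot/outside-comfort accident probabilities by
    Monte Carlo simulation, and ranks the relative importance of the four
    environmental inputs with a single-hidden-layer neural network. A
    synthetic registry generator emulates a monsoon-climate accident and
    weather feed so the full pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    nnet,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
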