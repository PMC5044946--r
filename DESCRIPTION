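Package: irribucket
Title: Soil-Water Bucket Modelling of Crop Irrigation Demand Under Climate Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A daily soil-water bucket model with threshold-triggered
    irrigation for estimating crop irrigation demand on sandy arable
    soils. Couples a crop calendar and rotation scheduler to the water
    balance, accounts annual irrigation totals against a groundwater
    abstraction cap evaluated as a trailing 7-year moving average, and
    tests annual series for monotonic trends with Kendall's tau-b
    (Mann-Kendall) and ordinary least squares. Includes a seedable
    stochastic weather generator (Markov-chain precipitation occurrence
    with gamma amounts, configurable temperature and evapotranspiration
    trends) and an FAO-56 Penman-Monteith reference evapotranspiration
    routine, so multi-decade scenario experiments can be run without
    proprietary climate data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
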