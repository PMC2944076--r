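Package: airburden
Title: Global Mortality Burden of Anthropogenic Ozone and Fine Particulate Matter
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates premature mortality and years of life lost attributable
    to anthropogenic ground-level ozone and fine particulate matter (PM2.5)
    from gridded present-day and preindustrial surface concentration fields.
    Implements log-linear health impact functions (relative risk, attributable
    fraction, excess mortality, years of life lost), the 6-month seasonal
    daily 1-hr maximum ozone exposure metric, PM2.5 mass reconstruction from
    speciated aerosol components, low and high concentration threshold
    handling, demographic regridding from country and region tables, Monte
    Carlo propagation of concentration-response and concentration uncertainty,
    and regional burden reporting. Ships a synthetic-world generator that
    emulates the statistical structure of chemical transport model output,
    gridded population, and vital-statistics inputs so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
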