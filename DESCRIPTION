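Package: hinequity
Title: Income-Related Inequality and Horizontal Inequity in Unmet Healthcare Needs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures income-related inequality and horizontal inequity in
    binary unmet-healthcare-need outcomes (postponed and denied care) from
    weighted survey extracts. Implements weighted fractional income ranks,
    standard, generalized and Erreygers-corrected concentration indices with
    heteroskedasticity-robust standard errors via the convenient-regression
    device, weighted probit models with partial effects at sample means, the
    need/non-need decomposition of the corrected concentration index, the
    horizontal inequity index, and bias-corrected bootstrap confidence
    intervals. Ships a configurable synthetic survey generator with a probit
    data-generating process so the whole pipeline is testable without
    restricted-access survey microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
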