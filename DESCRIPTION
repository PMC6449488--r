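Package: mobhaz
Title: Month-of-Birth Misreporting Artifacts in Child Height-for-Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and diagnostic tools for misreported month of birth
    (MOB) in child anthropometry surveys. Generates benchmark cross-sectional
    girl populations from a shipped growth-standard reference with slowed
    growth velocity and rescaled dispersion, injects random-within-year MOB
    errors and asymmetric round-age rounding, computes the calendar-year
    (December-January gap) and round-age artifacts in height-for-age z-scores
    (HAZ), calibrates the share of children with a random MOB from an observed
    gap, quantifies the resulting bias in stunting rates, and traces the bias
    that MOB misclassification induces in estimated effects of early-life
    shocks on HAZ and test scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
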