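Package: tripleiso
Title: Data Reduction for Triple Stable Isotope Analysis of Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduction of raw isotope-ratio mass spectrometry (IRMS) run
    sequences from high-temperature conversion (HTC) analysis of cellulose,
    sugars and bulk organic matter to calibrated delta-13C, delta-18O and
    nonexchangeable delta-2H values. Implements first-order memory
    correction, position-based linear drift correction, two-point scale
    normalization to VSMOW/VPDB (absorbing the constant reactor-carbon
    contribution to CO in HTC delta-13C analysis), and the exchangeable
    hydrogen correction from water-vapour equilibration, together with
    quality-control statistics, reactor comparison tables, a nitrogen-bias
    screen, and a seeded forward simulator of instrument runs with known
    truth for validating every correction stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
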