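Package: liquidus
Title: Mapping Oleogel Phase Diagrams from Variable-Temperature 1H NMR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative variable-temperature 1H NMR mapping of
    concentration-temperature phase diagrams of oleogels. From a single gel
    sample measured over a temperature ramp, the soluble gelator fraction is
    recovered from peak integrals normalized to an internal standard,
    corrected for solvent overlap via a bounded floor-offset adjustment, and
    converted between deuterated and protiated solvent weight-fraction bases.
    The package assembles the liquidus line with a quadrature error budget and
    a reliability flag, detects polymorphic gel-gel transitions as
    concentration-independent corner points, and ships a seeded synthetic
    spectrum generator with exported ground truth so the full pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
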