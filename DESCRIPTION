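Package: scedrf
Title: Response-Function Randomization Tests for Single-Case Experimental Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Randomization tests for randomized single-case experimental
    designs (SCEDs) with test statistics built from predicted response
    functions.  A response function is a vector of constants describing the
    expected response at every measurement occasion: immediate or delayed
    onset, abrupt or gradual progression, permanent or temporary duration,
    optional baseline trend, optional upper asymptote, or fully user-defined
    shapes.  Pearson's product-moment correlation between the observed series
    and the response function is used as the test statistic, the
    randomization distribution is obtained by exact enumeration of the
    admissible data divisions implied by the design's randomization scheme
    (random intervention start point for A-B designs, Wampold-Worsham and
    Koehler-Levin multiple-baseline schemes, phase-change enumeration for
    reversal designs, and block randomization for alternating treatments
    designs), and one-sided rank-based p-values are reported.  Exploratory
    scans over effect latencies and effect durations, multiplicity
    adjustment, a synthetic-data generator for the prototypical effect
    patterns, and power/validity simulation harnesses are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
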