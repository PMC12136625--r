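Package: fert3414
Title: Analysis of '3414' NPK Formula-Fertilization Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the '3414' soil-testing and formula-fertilization
    trial design (three factors N, P2O5, K2O at four levels in fourteen
    treatments). Builds the canonical design, reads and writes plot-level
    trial tables, fits unary/binary/ternary quadratic fertilizer effect
    functions by ordinary least squares, classifies them against the law
    of diminishing returns, and locates maximum-yield and economic-optimum
    doses. Implements relative-yield nutrient abundance indexing,
    output-value and profit-to-investment economics, and yield-frequency
    analysis for recommended dose ranges with confidence intervals.
    Includes a synthetic-trial generator with a known quadratic response
    surface for parameter-recovery studies, and a one-call pipeline that
    writes a full report bundle. Ships a worked honeysuckle (Lonicera
    japonica) trial as the canonical example data set.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
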