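Package: gpsmets
Title: Oxygen Consumption and Energy Expenditure from GPS Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates oxygen consumption (VO2) and energy expenditure for
    walking and running from timestamped GPS tracks. Adjacent track points are
    converted to segments carrying speed and slope; per-segment exercise
    intensity comes from a piecewise log-linear METs model of speed combined
    with a quadratic gradient-cost multiplier, and is accumulated to MET-hours,
    cumulative VO2 (ml/kg and litres) and kilocalories. The ACSM walking and
    running metabolic equations are included as reference methods, together
    with a method-agreement suite (relative error with t-based confidence
    intervals, Bland-Altman bias and limits of agreement), a pluggable
    elevation provider with an offline raster grid, and a seeded synthetic
    track generator with closed-form expected outputs for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
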