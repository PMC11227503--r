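Package: pspcensus
Title: Permanent Sample Plot Census Management and Forest Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the full data lifecycle of long-term tropical forest
    permanent sample plot (PSP) censuses: a relational flat-file archive
    schema (eight CSV tables plus two GeoJSON spatial layers) with validated
    readers and writers, girth-to-diameter measurement conversion with field
    rounding rules, post-campaign quality-control screening of diameter
    increments, a deterministic correction engine for height-of-measurement
    (hom) raises (taper-ratio conversion), diameter gap filling and re-born
    trees, plot-level forest dynamics statistics (stem density, basal area,
    annualized mortality and recruitment rates), and a synthetic census
    generator with exhaustive ground-truth logging for testing every stage
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
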