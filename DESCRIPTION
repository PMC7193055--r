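Package: ovimove
Title: Sheep Movement Data Analysis for Slaughterhouse-Based Surveillance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing statutory batch-level sheep movement
    records to support the design and interpretation of slaughterhouse-based
    surveillance. Builds deduplicated slaughter populations from dual-recorded
    market legs, classifies movements into within/out-of/into-country classes,
    estimates slaughterhouse catchment areas on a fixed-area hexagonal grid,
    scores the spatial representativeness of convenience samples with a
    per-cell chi-square rule, constructs regional origin-destination matrices
    with seasonal slices, and fits a Poisson generalised linear model of batch
    size by movement class. A synthetic movement-data generator reproduces the
    statistical structure of national traceability data (dual market records,
    mis-reads, batch-only animals, seasonal peaks) together with ground truth
    for every pipeline stage, so the full analysis is testable without access
    to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
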