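Package: geldens
Title: Reproducible Gel and Western Blot Densitometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, fully scriptable densitometry engine for gel
    electrophoresis and Western/Southern blot images. Supports image
    cropping and polarity handling, whole-image background subtraction
    (flat-disc rolling ball and percentile methods), straight or curved
    lane paths with per-node widths, per-row lane intensity profiles,
    per-lane piecewise-linear baselines, bounded integration into raw
    measurement values, and loading-control normalization against
    designated reference lanes. Every analysis step is recorded with its
    complete parameters in an embedded SQLite store so that any result can
    be replayed bit-identically and exported to spreadsheets. A
    deterministic synthetic gel-image generator with known per-band ground
    truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    digest,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    jpeg,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
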