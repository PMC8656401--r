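Package: elandscape
Title: Energy Landscape Analysis of Binarized Brain-State Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits pairwise maximum entropy (Ising) models to binarized
    multichannel signals such as region-of-interest BOLD time series, maps the
    resulting energy landscape (basin states, attraction clusters, minimax
    energy barriers, disconnectivity dendrograms, concentric-circle landscape
    profiles), and quantifies participant-level dynamics on that landscape
    (basin occurrence frequencies, transition and staying rates, traveling and
    lingering scores) with group-comparison statistics. Includes a synthetic
    cohort generator with planted landscapes so every stage of the pipeline can
    be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
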