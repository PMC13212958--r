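Package: mycospike
Title: Detection and Propagation Analysis of Slow Electrical Spikes in
    Fungal Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing slow extracellular electrical activity
    recorded from fungus-colonised substrates with linear multi-electrode
    arrays. Detects millivolt-scale spikes lasting tens of seconds to tens
    of minutes using a median-baseline amplitude threshold combined with a
    minimum-duration rule, summarises spike morphology and inter-spike
    interval statistics including burst clustering, and quantifies
    directional propagation along the array via onset-association delay
    matrices, robust delay-versus-distance velocity fits, permutation
    surrogate controls, and threshold sensitivity analysis. Includes a
    seeded synthetic multichannel recording generator with ground truth so
    every analysis stage can be validated without access to original
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
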