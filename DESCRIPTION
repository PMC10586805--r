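Package: larvahab
Title: Habituation Analysis of Drosophila Larva Vibration Responses
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for the behavioral response of crawling
    Drosophila larvae to pulsed vertical vibration. Classifies continuation,
    pause, turn and reverse-crawl events from tracked trajectories, computes
    population response fractions and individual behavioral transition
    matrices, fits exponential de-sensitization and re-sensitization models
    with parametric-bootstrap uncertainties, contrasts the observed dynamics
    with a linear time-invariant impulse-response prediction, and simulates a
    capacitor-switch circuit analog of habituation. A seeded synthetic-data
    generator produces response records, binned count series and geometric
    trajectories with the statistical structure the analysis assumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
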