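Package: puzzletrain
Title: Adaptive Puzzle-Game Cognitive Training Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for adaptive puzzle-game cognitive training.
    Implements parameterized match-3 and numberlink puzzle engines, a
    regression-based dynamic difficulty-adaptation service (solving-time
    prediction plus a thresholded -1/0/+1 level predictor), synthetic players
    with lognormal response times and practice effects, time-based performance
    metrics, and the statistical analysis of a small crossover trial with the
    participant, motivation and workload tables embedded as fixtures.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
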