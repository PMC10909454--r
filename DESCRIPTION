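Package: ciconia
Title: Movement Ecology Pipeline for Partially Migratory White Storks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to analyse GPS/accelerometry biologging data from a
    partially migratory white stork population: overall dynamic body
    acceleration (ODBA) from tri-axial bursts, random-forest behaviour
    classification (foraging, resting, soaring, flapping), rule-based
    trajectory segmentation into four migratory strategies and four
    seasons, breeding phenology extraction from nest attendance, and a
    multievent capture-recapture hidden Markov model for joint estimation
    of survival, GPS signal loss, and resighting probabilities with
    overdispersion-corrected QAICc model selection. A synthetic-data
    generator with ground-truth records makes every stage testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ranger,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    geosphere,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
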