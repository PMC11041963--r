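Package: pulsetherm
Title: Remote Photoplethysmography, Facial Thermal Features and Multimodal Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts pulse and heart-rate-variability measures from
    multi-region facial RGB mean-intensity traces using the
    plane-orthogonal-to-skin (POS) projection, windowed spectral heart-rate
    estimation, a 25-BPM jump filter and an MAE/HR signal-quality index;
    derives per-region facial temperature change features over 120-s
    segments; and fuses the two modalities with early- and late-fusion
    classifiers, Monte-Carlo Shapley feature importance, quality-threshold
    sweeps and cross-modal correlation maps. Includes seeded synthetic-data
    generators with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    rpart,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
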