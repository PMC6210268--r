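Package: imubehave
Title: Classification of Sheep Eating Behaviour from Inertial Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for classifying grazing, ruminating and non-eating
    behaviour of sheep from 16 Hz tri-axial accelerometer and gyroscope
    streams recorded at the ear or the collar. Builds four derived channels
    (accelerometer and gyroscope magnitudes and their rates of change),
    discretises them into overlapping 7 s windows labelled from a behaviour
    interval track, extracts 11 time- and frequency-domain characteristics
    per channel (44 features per window), ranks the features with multiclass
    ReliefF, compares random forest, support vector machine, k-nearest
    neighbour and AdaBoost learners under stratified 10-fold
    cross-validation, and derives precision, recall, F-score and specificity
    from multiclass confusion matrices. Ships a seeded synthetic-trial
    generator so the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
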