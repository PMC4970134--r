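Package: vennmachine
Title: Venn Machine Multiprobability Prediction for Gas-Sensor Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Calibrated multiprobability classification for electronic-nose
    data. Implements the Venn machine transductive framework, which wraps any
    underlying classifier (Gaussian naive Bayes, softmax regression, or a
    support vector machine with Platt scaling and pairwise coupling) as a
    taxonomy and returns, for each test sample, a predicted class together
    with a probability interval whose validity is guaranteed under the i.i.d.
    assumption alone. Also provides transient feature extraction for
    metal-oxide sensor-array recordings (maximal response, curve integral,
    exponential-moving-average derivative features), min-max feature scaling,
    leave-one-out and online evaluation protocols, calibration diagnostics
    (mean log loss, root mean square loss, cumulative-probability deviation)
    with minimax interval-to-point conversions, and a synthetic generator for
    multi-class sensor-array experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    graphics,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
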