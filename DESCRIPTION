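Package: findface
Title: Adaptive Chart-Based Estimation of Face Discrimination Thresholds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring the face-space distance at which two faces
    are perceived as different people, using a chart-based adaptive
    procedure grounded in signal detection theory. Faces are represented as
    coordinate vectors in a 199-component morphable face space; charts of
    face pairs are generated, yes/no responses are classified as hits,
    misses, false alarms and correct rejections, and a saturating d-prime
    psychometric function is fit by weighted nonlinear least squares to
    place subsequent stimuli at informative discriminability levels.
    Includes simulated observers (single-channel and Euclidean-combination)
    for closed-loop parameter recovery, probability-summation analysis of
    single versus combined component thresholds, Bland-Altman test-retest
    assessment, and CSV/JSON/YAML interchange with external presentation
    front-ends and renderers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
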