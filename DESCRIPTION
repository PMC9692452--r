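Package: ergorula
Title: Automated RULA Ergonomic Assessment from Body and Hand Tracking Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated Rapid Upper Limb Assessment (RULA) from multimodal
    skeleton-tracking data. Fuses a body-tracking stream (16 joints, 30 Hz)
    and a hand-tracking stream (25 joints per hand, 64 Hz) onto a common grid
    with Piecewise Aggregate Approximation, computes wrist kinematics
    (flexion-extension, radial-ulnar deviation, pronation-supination) and
    body-segment joint angles by vector geometry, maps them to RULA segment,
    section and grand scores with risk levels, and evaluates agreement with
    expert labels via a similarity statistic plus across-subject one-way
    ANOVA and pairwise t-tests. Includes a synthetic skeleton-session
    generator with known ground-truth angles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
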