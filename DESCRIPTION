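Package: padrom
Title: Mobility Restriction and Comfort Analysis of Protective Pads from
    Quaternion Motion Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how protective equipment such as
    ice hockey shoulder and elbow pads restricts upper-body mobility, and how
    that restriction relates to subjective comfort. Converts frame-wise
    unit-quaternion segment orientations from inertial motion capture into
    joint angles (relative joint quaternions decomposed in the intrinsic YXZ
    order), applies zero-phase Butterworth smoothing, extracts range of motion
    for static single-joint tasks and event-segmented shooting motions,
    runs repeated-measures ANOVA with Greenhouse-Geisser correction, LSD
    post-hoc comparisons and partial eta-squared effect sizes, analyses Likert
    comfort surveys with Friedman and Wilcoxon signed-rank tests, and
    correlates comfort with total range of motion. Includes a synthetic study
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
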