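Package: critweight
Title: Breakpoint Estimation of the Critical Weight Checkpoint in Insect Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the nutrition-dependent critical weight checkpoint in
    Drosophila larvae from starvation-response experiments. Fits a continuous
    two-segment (hinge) regression of time-to-pupariation on age at starvation,
    taking the breakpoint as the age at critical weight; converts ages to masses
    through a linear larval growth curve; builds case-bootstrap percentile
    confidence intervals for age and mass at critical weight; compares groups
    with age-stratified permutation tests; performs relative qPCR quantification
    (delta-delta-Ct against an internal control and calibrator) and
    sliding-window compact-letter-display comparisons of time courses; and
    generates synthetic cohorts with the assumed statistical structure so the
    whole pipeline can be exercised and calibrated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
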