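Package: pedipose
Title: Pose-Based Pediatric Weight Estimation and Agreement Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates pediatric body weight from human pose keypoints and
    demographic metadata. Skeletal edge distances computed from 17 named
    2-D keypoints are concatenated with sex, age and visually assessed
    body type and fed to a small feedforward regression network whose
    height estimate is converted to weight through a growth-reference
    table with body-type percentile bands. Ships a Broselow-style
    length-zone baseline, a seeded synthetic pediatric cohort and pose
    renderer for end-to-end testing, and the full method-agreement
    battery: MPE, MAPE, RMSPE, PW10/PW20, Bland-Altman limits of
    agreement, and two-way absolute-agreement intraclass correlation
    with F-based confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
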