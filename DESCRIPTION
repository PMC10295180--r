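Package: herdtrack
Title: Tracking-by-Detection and Behavior Analytics for Barn-Housed Cattle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for monitoring individual cattle in fixed-camera barn
    footage from per-frame detector output. Implements sliding-window action
    majority voting to stabilize behavior labels, tracking-by-detection with a
    constant-velocity Kalman filter, combined Mahalanobis/cosine appearance
    association with Hungarian assignment, long-gap appearance
    re-identification, per-identity and herd-level behavior statistics and
    trajectory reports, CLEAR-MOT/IDF1/HOTA evaluation against MOT Challenge
    ground truth, and a seeded synthetic barn-scene generator for testing the
    full pipeline without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
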