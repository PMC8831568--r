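Package: mearaster
Title: Raster-Plot Machine Learning for Seizure-Liability Screening on
    Multiwell MEA Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Converts multiwell microelectrode-array (MEA) spike recordings
    into raster-plot images windowed by each well's baseline network-burst
    rhythm (four times the inter-maximum-frequency interval, IMFI), extracts
    4096-dimensional deep-style image features normalized per well against
    the vehicle epoch, and trains shallow pattern-recognition networks to
    predict seizure liability concentration-dependently and to identify
    compounds. Includes network-burst detection with the five standard burst
    parameters (TS, NoB, IBI, DoB, SiB), percent-of-control dose-response
    tables with Dunnett tests against vehicle, ROC analysis with a
    cost-slope optimal operating point, linear / one-class / multi-class
    support-vector-machine baselines, grouped holdout and
    leave-one-well-out validation, and a fully seeded synthetic-data
    generator emulating 24-well, 16-electrode cumulative-administration
    experiments so the whole pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    multcomp,
    withr,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    ggplot2
Config/testthat/edition: 3
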