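Package: dynpeak
Title: Multiscale Pulse Detection and Interpulse-Interval Analysis for
    Hormonal Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects secretory pulses in sparsely sampled hormonal time
    series (typically luteinizing hormone assayed every 10 minutes) using a
    multiscale, multi-criteria selection of local maxima that is robust to
    baseline drift: height and magnitude criteria built on geometric means,
    retrieval of missed pulses, and removal of overly sharp 3-point peaks.
    The interpulse-interval (IPI) series is monitored against a cubic trend
    surrounded by a configurable tunnel, flagging candidate lacks of
    detection, over-detections and rhythm breaks.  A generative model of
    pulsatile pituitary release, first-order plasma clearance, jittered
    periodic sampling and multiplicative assay noise is included to produce
    synthetic series with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
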