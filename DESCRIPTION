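Package: stwhrv
Title: Sliding-Time-Window Feature Extraction from Heart Rate Variability for Nociception Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects noxious stimulation (tracheal intubation) under general
    anesthesia from beat-to-beat RR-interval recordings. Implements cubic-spline
    resampling of RR tachograms to a uniform rate, empirical mode decomposition
    by envelope-mean sifting, recombination of intrinsic mode functions into
    high-frequency (0.15-0.4 Hz) and low-frequency (<0.15 Hz) component signals,
    sliding-time-window endpoint-difference feature extraction with a window-size
    sweep, and binary detectors (a transparent threshold rule and a small
    recurrent network baseline). Includes a seeded synthetic RR-tachogram
    generator emulating the statistical structure of intubation recordings so
    the full pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
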