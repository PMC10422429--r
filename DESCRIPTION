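Package: beetraffic
Title: Omnidirectional Bee Traffic Quantification from On-Hive Video
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies omnidirectional honey bee traffic at the hive
    entrance from video frame sequences. Detects inter-frame motion
    regions with a frame-differencing operator chain (grayscale,
    Gaussian blur, absolute difference, dilation, binary threshold,
    contour extraction with area filtering), aligns detector-produced
    bee boxes to motion-region centers by kd-tree radius queries, and
    scores pipeline output against ground truth with a seven-category
    confusion taxonomy and its derived precision/recall/F1/IoU metrics.
    Also provides energy-efficacy and operational energy-footprint
    accounting for monitoring deployments, a pluggable detector
    interface with a configurable synthetic oracle detector, and a
    synthetic bee-flight scene generator implementing straight, zigzag,
    land-and-crawl and parallel flight patterns so every stage is
    testable without trained detector weights or field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
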