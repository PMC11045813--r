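Package: trawlcount
Title: Tracking-by-Detection Catch Counting for In-Trawl Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Real-time catch counting for in-trawl camera footage by
    tracking-by-detection. Provides a from-scratch SORT tracker
    (constant-velocity Kalman filter plus IoU-optimal assignment),
    horizontal-line crossing count rules for Norway lobster (Nephrops
    norvegicus) catches, fixed and adaptive frame-skipping schedulers with
    effective-FPS bookkeeping, counting-accuracy evaluation metrics
    (correct count rate, F-score), a seeded synthetic scene generator that
    emulates in-trawl footage, and a replay pipeline with a command-line
    interface. No neural network is bundled; detections are replayed from
    MOT-style CSV files or generated synthetically.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
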