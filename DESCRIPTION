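Package: flybouts
Title: Rule-Based Detection and Evaluation of Drosophila Aggression and
    Courtship Behaviors from Two-Fly Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying dyadic Drosophila social behavior from
    tracker-exported trajectories. Provides validated containers and CSV
    readers for two-fly pose tables, per-frame kinematic and dyadic feature
    extraction (speed, inter-fly distance, facing and rear angles, angular
    position and sideways motion), rule-based detectors for six behaviors
    (lunge, wing extension, following, circling, attempted copulation and
    copulation) with persistence filtering and a duration-floor post-filter,
    bout-level and frame-level precision/recall/F1 evaluation against manual
    annotations, behavioral indices, and a deterministic synthetic session
    simulator with an annotation corrupter for end-to-end testing. A command
    line entry point covers the simulate/classify/evaluate workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    jsonlite,
    optparse,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
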