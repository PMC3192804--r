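Package: reachioc
Title: Inverse Optimal Control of Redundant Arm Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying which movement costs the central nervous
    system optimizes during planar arm reaching toward a redundant target
    (a vertical bar). Implements a two-link arm model under gravity with a
    torque-derivative actuator, eight classical movement cost functionals
    (hand jerk, angle jerk, angle acceleration, torque change, torque,
    geodesic, absolute-work energy, neural effort) and their weighted
    composites, a direct optimal-control solver based on an
    inverse-dynamics spline transcription, and a bi-level inverse
    optimal-control procedure that recovers the cost-weight vector best
    explaining observed trajectories. Includes a motion-analysis toolbox
    (filtering, movement segmentation, curvature and consistency indices,
    Monte-Carlo path-area comparison) and a synthetic-data generator that
    emulates rest-to-rest reaching recordings, so the full pipeline can be
    exercised end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    mgcv,
    minqa,
    pracma,
    signal,
    splines,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
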