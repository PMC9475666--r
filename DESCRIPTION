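Package: lungeforge
Title: Biomechanics and Energetics of Rorqual Lunge Feeding from Biologging Data
Version: 0.1.0
Authors@R:
    person("Lungeforge", "Developers", email = "lungeforge@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing rorqual whale lunge feeding from animal-borne
    tag kinematics (depth, pitch, speed, gyroscope at 10 Hz) and aerial
    morphometrics. Segments deployments into lunges and extracts the six
    canonical event times and phase durations; computes engulfed water volume
    from a prescribed gape schedule (posterior integral plus anterior
    ellipsoid), engulfment drag, and the shape-drag-minus-thrust force
    residual; estimates per-lunge metabolic cost (fluke, parasitic, ventral
    groove blubber, and ceteral terms), energetic gain from prey, and foraging
    efficiency at lunge, dive, and day timescales; fits log-log allometric
    regressions and compares slopes; and ships a seeded synthetic deployment
    generator with ground-truth lunge annotations for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
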