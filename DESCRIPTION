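Package: cogniphys
Title: Neurophysiological Feature Extraction and Neuro-Fuzzy Cognitive State Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating operator cognitive states (such as mental
    workload) from wearable and remote neurophysiological sensors. Extracts
    oculomotor events and gaze metrics (fixations, saccades, dwells, blinks,
    transition entropy, nearest-neighbour index, pupillometry) from raw gaze
    streams, time-, frequency- and geometric-domain heart rate variability
    from inter-beat interval series, and respiratory rate/volume metrics from
    strain-gauge traces. A Sugeno-type neuro-fuzzy inference engine maps the
    extracted features to cognitive state estimates, supports least-squares
    calibration against labelled sessions, and propagates sensor measurement
    uncertainty to the state estimate by first-order (delta-method) analysis
    validated against Monte-Carlo simulation. Sensor characterisation
    statistics (angular accuracy and precision, field-of-view uncertainty,
    blink-rate error, validity against a reference device) and seeded
    synthetic-signal generators for gaze, cardiac, respiratory and paired
    sensor data complete the sensing-to-estimation chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
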