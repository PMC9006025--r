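Package: gesturekit
Title: Multi-Scale Analysis of Gesture Kinematics, Speech Acoustics and
    Speech-Gesture Coupling Under Degraded Visibility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how co-speech gesture and speech adapt
    to parametrically degraded visual quality in dyadic conversation.
    Provides readers for 2-D pose-tracker keypoint trajectories, gesture
    annotations and mono WAV audio; articulator-level motion energy with
    reference-articulator correction; signal-level gesture kinematics
    (peak velocity, submovements, hold-time, size, McNeillian space,
    depth, nPVI) and speech acoustics (amplitude envelope, maximum
    intensity, maximum F0); cross-wavelet coherence and phase asynchrony
    between the speech envelope and hand velocity in the 2-8 Hz band with
    surrogate-based significance; polynomial mixed-model comparison
    ladders with pseudo-R-squared and a correlation-adjusted alpha; and a
    synthetic dyad generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    lme4,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    car,
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
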