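Package: ppgpress
Title: Contact-Pressure Effects on Reflectance Photoplethysmography Signals
Version: 0.1.0
Authors@R: person("PPG", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how sensor contact
    pressure affects reflectance photoplethysmography (PPG) signals. Generates
    phantom-like multi-channel recordings (red/infrared PPG, load-cell force,
    inline blood pressure) with known ground truth, conditions them with
    zero-phase IIR and linear-phase FIR low-pass filters, tracks per-second
    signal-to-noise ratio against contact pressure to locate the optimum
    sensor pressure, automatically segments the pulsatile portion of a
    recording via a rectified-envelope procedure, detects cardiac cycles and
    tangent-intersection fiducial points, extracts 17 morphological pulse
    features, and ranks feature robustness to contact pressure by Spearman
    correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
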