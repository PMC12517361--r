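Package: uncrowdr
Title: Recurrent-Segmentation Modelling of Vernier Crowding and Uncrowding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates the vernier/flanker stimuli used in spatiotemporal
    crowding experiments, simulates a simplified two-layer recurrent
    segmentation model (top-down selection signals spreading along
    connected contours, transfer of selected contours to a second
    segmentation layer, template-contrast evidence readout), and runs a
    full adaptive psychophysics pipeline (PEST staircase, cumulative
    Gaussian threshold fits, simulated observers) to turn model evidence
    into predicted vernier discrimination thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
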