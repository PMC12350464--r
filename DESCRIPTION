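Package: stenoscope
Title: Subglottic Stenosis Severity Estimation from Bronchoscopy Video
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Automated estimation of subglottic stenosis severity from
    bronchoscopy image sequences. The airway lumen is segmented as the
    darkest image region and tracked with an intersection-over-union
    tracker until the camera passes the vocal cords; at that keyframe a
    single-frame, up-to-scale 3D reconstruction is computed from the
    inverse-square decline of illumination, and stenosis indices (percent
    stenosis by area, PSA, and by diameter, PSD) are derived from
    cross-section areas and fitted-circle diameters. Includes a synthetic
    stenotic-airway phantom renderer with ground-truth depth so the whole
    pipeline can be validated without clinical data, plus evaluation
    utilities (keyframe correctness, mean absolute error, same-patient
    consistency).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
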