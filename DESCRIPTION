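Package: larvacast
Title: Head-Cast and Turn Analysis for Larval Light-Spot Phototaxis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments and classifies Drosophila larval head-cast and turning
    behaviour from tracked body-point time series recorded in a light-spot
    phototaxis assay. From per-frame head, midpoint, tail and centroid
    coordinates the package derives the standard kinematic signals
    (tailspeed, headtheta, headomega, bodytheta, bodyomega), detects stop
    periods by a tail-speed threshold, detects head casts as supra-threshold
    angular-speed peaks, assembles casts and body-reorientation peaks into
    1-cast and n-cast turn events, scores light-avoidance success against a
    scatter-expanded light-spot geometry, and summarises success, acceptance
    and amplitude statistics with exact and t tests. A scripted trajectory
    simulator generates ground-truth-labelled fixtures so the whole pipeline
    is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    pracma,
    signal,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
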