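Package: speechdpoae
Title: Speech-Elicited Distortion-Product Otoacoustic Emissions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesis and detection of distortion-product otoacoustic
    emissions (DPOAEs) elicited by harmonics of running speech. Builds
    narrowband waveforms locked to the time-varying fundamental frequency
    of a speech signal, shifts them to arbitrary harmonics through the
    analytic (Hilbert) representation, detects the cubic distortion
    product in an ear-canal microphone recording by normalized complex
    cross-correlation, and quantifies attentional modulation of the
    emission amplitude with bootstrap and rank-based inference. Includes
    a virtual-ear simulator with known distortion amplitude, latency and
    phase so that every stage of the pipeline can be validated without
    hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
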