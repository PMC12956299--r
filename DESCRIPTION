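Package: mux2p
Title: Temporal Demultiplexing and Fluorescence Lifetime Analysis for
    Multiplexed Two-Photon Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Software companion to an FPGA-based multiplexed two-photon
    mesoscope: simulates high-rate digitizer streams carrying fluorescence
    from four temporally interleaved excitation paths, slices and
    gate-integrates pulses into per-channel counts, removes inter-channel
    leakage with a circulant mixing model, reconstructs sinusoid-corrected
    images from resonant-scanner sync events, and estimates fluorescence
    lifetimes per pixel by IRF-convolution least squares, Poisson maximum
    likelihood, phasor analysis, and a genetic-algorithm-optimized
    four-gate method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    zoo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
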