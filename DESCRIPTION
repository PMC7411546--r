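Package: ocistc
Title: Spatial Tuning Curve Analysis for Multi-Channel Optical Cochlear
    Implant Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies spectrally selective activation of the auditory
    nerve in multi-channel optical cochlear implant experiments recorded
    with linear probes in the auditory midbrain. Provides multi-unit spike
    extraction from extracellular voltage traces (4th-order Butterworth
    band-pass, median plus three median-absolute-deviations threshold,
    refractory enforcement), peri-stimulus time histograms and response
    window detection, frequency response areas with characteristic
    frequency extraction and per-animal tonotopic slope calibration,
    cumulative d-prime response matrices, spatial tuning curves with
    activation thresholds, best-electrode and spread-of-excitation
    estimation, tonotopic place-code regression with spatial-to-spectral
    conversion, and a fully seeded synthetic-data generator that emulates
    micro-LED based optogenetic stimulation of the cochlea in hearing,
    deafened and wild-type animals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
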