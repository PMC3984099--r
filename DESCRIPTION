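Package: spikecodec
Title: Transform Coding and Evaluation of Extracellular Spike Waveforms for
    Wireless Brain-Machine Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ground-truth multi-channel extracellular recordings,
    detects and extracts spike waveforms with absolute-value (ABS) or
    nonlinear-energy-operator (NEO) detectors, aligns them with
    fractional-delay filters, compresses and reconstructs them by transform
    coding with SVD-derived, Haar and downsampling bases, sorts them with
    PCA features and K-means, and evaluates reconstruction accuracy, sorting
    accuracy, combined score, minimum coefficient count, implant-side
    computational complexity and wireless data-rate budgets across candidate
    implant/external system architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
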