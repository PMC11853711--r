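Package: frckit
Title: Frequency Response Cooperativity Analysis of QCM-D Adsorption Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes time-resolved quartz crystal microbalance with
    dissipation (QCM-D) adsorption curves into a spectrum of cooperative
    sigmoidal kinetic components on a log-spaced grid of apparent rate
    constants (the Frequency Response Cooperativity model). Includes the
    standard preprocessing chain for multi-overtone frequency/dissipation
    records (dissipation-based quality filtering, overtone averaging,
    baseline zeroing, representative-replicate selection), Gaussian peak
    deconvolution of the resulting kinetic spectra, Hill-equation
    cooperativity and binding free-energy analysis, Langmuir model
    comparison, and a seeded synthetic-data generator with known ground
    truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
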