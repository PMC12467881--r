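Package: libsbridge
Title: Cross-Instrument Calibration Transfer and Classification for LIBS Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Harmonizes laser-induced breakdown spectroscopy (LIBS) emission
    spectra acquired on spectrometers of different resolution and spectral
    response, so that a classifier trained on one instrument can score spectra
    from another. Implements standard-lamp spectral response correction,
    ANOVA F-value feature ranking with incremental feature selection,
    random-forest classification under single- and cross-instrument
    protocols, and DBSCAN-based removal of abnormal test spectra with
    K-distance-graph parameter selection. Ships a two-instrument synthetic
    LIBS simulator (Gaussian emission lines, instrument response and echelle
    ripple, wavelength registration shifts, shot noise, planted outliers) so
    the whole pipeline is testable end to end without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    signal,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
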