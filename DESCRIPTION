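Package: diaphragmUS
Title: Quantitative Diaphragm Ultrasound and Muscle Physiology for Preclinical Dystrophy Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of diaphragm ultrasonography and ex vivo
    muscle physiology readouts in mouse models of muscular dystrophy.
    Provides B-mode echodensity quantification over outlined regions of
    interest, a per-column Canny-edge analysis of the superficial abdominal
    wall band to assess depth attenuation of the ultrasound signal, M-mode
    diaphragm excursion (amplitude) extraction from position traces,
    specific-force normalisation and eccentric-contraction metrics for
    isolated muscle strips, and the statistical battery used for such
    studies (one-way ANOVA with Bonferroni post hoc tests, unpaired t,
    Fisher variance-ratio operator agreement, Pearson correlation with
    linear fits). A synthetic-data module generates speckled B-mode
    phantoms, breathing traces and correlated cohorts with known ground
    truth so that every estimator has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    png,
    tiff,
    yaml,
    jsonlite,
    MASS,
    signal
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
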