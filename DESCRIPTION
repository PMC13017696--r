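Package: preyJND
Title: Receptor-Noise-Limited Avian Vision Modelling and Predation
    Analysis for Weakly Warning-Coloured Prey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how chemically defended, weakly
    warning-coloured insect prey appear to avian predators, and for
    analysing the fitness consequences of conspicuousness. Implements a
    receptor-noise-limited model of tetrachromatic bird colour vision
    (cone quantum catches, von Kries chromatic adaptation, abundance-scaled
    Weber fractions, chromatic and achromatic just-noticeable-difference
    contrasts with threshold classification), reflectance-spectrum
    import/resampling/averaging, a contrast pipeline for stimulus
    comparisons against natural backgrounds, Cox proportional-hazards
    survival analysis of field predation experiments with a first-attack
    data filter, logistic mixed models (adaptive Gauss-Hermite quadrature)
    and gamma log-link models for defensive-behaviour phenotypes, and
    seeded synthetic-data generators for spectra, predation experiments
    and family-structured behaviour records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    lme4,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
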