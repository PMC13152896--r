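Package: uvmorph
Title: Detection and Visual Modelling of Cryptic UV-White Colour
    Polymorphism from Reflectance Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting cryptic ultraviolet colour polymorphism
    (UV-reflecting versus UV-absorbing white) from reflectance
    spectrophotometry. Provides a SummarizedExperiment-based container for
    reflectance spectra, colorimetric variables (luminance, UV chroma, hue,
    spectral cut-off R_mid) with threshold classification of white patches,
    a receptor-noise-limited tetrachromatic visual model (Govardovskii A1
    pigment templates, von Kries quantum catches, chromatic and achromatic
    just-noticeable differences), bootstrapped between-group centroid colour
    distances with confidence intervals, a distance-based PERMANOVA, a
    synthetic spectral cohort generator, and a reproducible end-to-end
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
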