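Package: eqctta
Title: Equilibrium-CT Filtration-Histogram Texture Analysis of Liver Fibrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Filtration-histogram CT texture analysis (CTTA) of pre-contrast and
    equilibrium-phase liver CT. Implements the Laplacian-of-Gaussian band-pass
    filtration step at configurable spatial scale filter (SSF) values, the six
    histogram statistics (mean, SD, entropy, mean of positive pixels, skewness,
    kurtosis), equilibrium-minus-pre subtraction features, extracellular volume
    fraction (ECV) computation from paired region-of-interest attenuations and
    haematocrit, and Spearman rank-correlation of every texture feature against
    fibrosis markers (collagen proportionate area, ECV, enhanced liver fibrosis
    score, Ishak stage). A seeded synthetic phantom generator produces paired
    pre/equilibrium slice cohorts with known severity links so the whole
    pipeline is testable end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
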