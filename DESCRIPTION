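Package: scoutreid
Title: Patient Re-Identification from Trunk Scout CT Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for biometric patient re-identification from 2D scout
    (localizer) CT projections of the trunk. Provides a synthetic
    scout-phantom generator with a projective table-height geometry model
    and vendor-specific contrast processing; the standard preprocessing
    chain (bicubic resampling to 2.0 x 2.0 mm, central 256 x 384 crop,
    linear 8-bit rescale); a geometric training augmentation pipeline
    including width-only random transversal scaling; a deep-metric-learning
    feature extractor (small convolutional backbone, nonlinear projection
    head, adaptive cosine-softmax classifier) trained with label-smoothed
    cross entropy and momentum SGD; cosine-similarity gallery matching; and
    the full identification evaluation protocol (top-K accuracy, CMC
    curves, vendor-pair stratification, genuine/impostor score
    distributions, two-proportion Z-test and McNemar's chi-squared test).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
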