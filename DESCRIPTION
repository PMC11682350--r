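Package: scentforge
Title: Inverse Design of Scent Recipes from Mass Spectra and Odor Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for algorithmic scent creation from unit-resolution mass
    spectra of essential oils. Decomposes a spectrum library into a small
    non-negative basis of odor components by Kullback-Leibler non-negative
    matrix factorization, trains a regularized feed-forward network that
    predicts binary odor descriptors from mass spectra (with mixture and
    noise data augmentation), and inverts the predictor by analytic-gradient
    descent over component mixing ratios to design recipes matching a target
    descriptor set. Includes chi-square statistics for two-alternative
    forced-choice and duo-trio sensory discrimination tests, and a synthetic
    library generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
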