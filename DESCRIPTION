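Package: redunet
Title: Dynamic Brain Functional Redundancy from Regional Timeseries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates brain functional redundancy (BFR) from parcellated
    BOLD-like regional timeseries: sliding-window Pearson correlation
    matrices are proportionally thresholded across a density grid, each
    window is labeled redundant when the network becomes two-connected at
    the same density at which it first becomes one-connected, and the
    proportion of redundant windows defines the BFR score. Includes
    principal component scoring of a cognitive test battery with
    line-distance elbow selection, multivariate moderation regressions
    testing whether BFR modulates the association between age-related
    brain-change measures and cognitive performance, and a synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
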