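Package: overnet
Title: Overlapping Brain Network Assignment, Reliability and Membership Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for defining and characterising overlapping intrinsic
    brain networks from resting-state functional connectivity. Builds sparse
    binary group connectomes from multi-subject correlation data
    (Fisher-z transform, proportional thresholding, subject averaging),
    assigns regions to K overlapping networks with an assortative
    mixed-membership stochastic block model fitted by batch variational
    inference, assesses between-sample reliability with Dice-coefficient
    permutation tests and optimal homologue matching, compares overlapping
    networks against nonoverlapping k-means networks, and quantifies each
    region's multiple-network membership with a scaled Kullback-Leibler
    relative-entropy statistic. Includes a synthetic-data generator with
    planted overlapping community structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
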