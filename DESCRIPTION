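Package: hcrprofile
Title: Line-Profile Quantification of Multiplexed HCR Expression Domains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis of multiplexed fluorescence in-situ
    (hybridization chain reaction) images of embryonic gene-expression
    domains. Turns multi-channel confocal stacks into normalized intensity
    line profiles along the medial-lateral axis, registers replicate
    profiles by Gaussian peak fitting on a reference channel, and averages
    them into mean +/- s.e.m. profiles. Provides overlap metrics that
    classify the spatial relationship between a query and a reference
    expression domain (overlapping, partial, flanking), a seeded synthetic
    stripe-image generator with analytic ground truth for validation, and
    supporting statistics (phenotype scoring proportions with Wilson
    intervals, delta-delta-Ct qPCR fold changes, Welch fold-change tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    tiff,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
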