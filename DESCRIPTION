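Package: fluctspec
Title: Mutation Rate and Spectrum Inference from Fluctuation Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation and comparison of spontaneous mutation rates from
    Luria-Delbruck fluctuation tests, and analysis of the mutational
    spectrum of rifampicin-resistance mutations in the rpoB gene.
    Implements the Lea-Coulson mutant-count distribution with mutant
    relative fitness, maximum-likelihood and P0 estimators of the
    expected mutation number, delta-method ("sigma method") ratio tests
    for rate plasticity between environments, semi-global alignment
    based variant calling of Sanger amplicon reads against the rpoB
    rifampicin-resistance determining region, and multinomial and
    per-class binomial logistic models with Type-II likelihood-ratio
    chi-square tests on the eight-category mutation spectrum. Includes
    a synthetic-study generator with known ground truth emulating a
    two-strain, two-glucose-level experimental design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    nnet,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
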