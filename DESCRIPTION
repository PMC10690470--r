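Package: stepDE
Title: Cumulative Step-Effect Negative-Binomial Time-Course Differential
    Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential expression analysis for treatment time courses of
    bulk 3'-UMI RNA-seq counts using a negative-binomial generalized linear
    model with a cumulative step-effect design: each time interval carries a
    persistent log2 increment shared by all arms (drift) plus
    treatment-specific increments, so treatment-versus-control contrasts at a
    time point are cumulative sums of interval effects. Includes
    median-of-ratios size factors, dispersion estimation with trend
    shrinkage, Wald contrasts with Benjamini-Hochberg adjustment,
    empirical-Bayes fold-change shrinkage under a zero-centered normal
    mixture prior, variance-stabilized PCA, gene-set over-representation
    analysis with redundancy-minimizing term selection, and a synthetic
    count simulator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse
Config/testthat/edition: 3
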