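Package: mirkron
Title: Kronecker Regularized Least-Squares Prediction of miRNA-Target
    Site Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts microRNA (miRNA) to mRNA target-site interactions
    from sequence-derived pairwise similarity kernels. Builds Gaussian
    interaction-profile, Needleman-Wunsch sequence, free-energy, site
    accessibility, AU-content and simple-sequence-repeat kernels over
    miRNAs and over target sites, integrates them by weighted
    combination, and scores every miRNA x site pair with a regularized
    least-squares model whose kernel is the Kronecker product of the two
    integrated similarity matrices, solved efficiently through the two
    small eigendecompositions. Includes leave-one-out and
    leave-sites-out cross-validation, ROC and confusion metrics,
    unity-based score normalization with quartile target classification,
    and a seeded synthetic-data generator that plants the family
    structure the method exploits (similar miRNAs share targets, similar
    sites share miRNAs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
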