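Package: epiheter
Title: Epistasis Detection, Subtype Discovery and Diagnosis for Heterogeneous Complex Diseases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A three-stage analysis framework for case-control SNP data in
    which complex disease arises from epistatic interactions and genetic
    heterogeneity. Stage one exhaustively scores k-order SNP combinations
    with mutual information and the K2 Bayesian score, keeps the Pareto
    non-dominated candidates and filters them by a Bonferroni-corrected
    chi-square test. Stage two clusters case samples on the detected
    epistatic SNPs with K-means to define disease subtypes. Stage three
    trains a feed-forward neural network (rectifier hidden layers, softmax
    output, dropout, mini-batch gradient training) for binary or subtype
    diagnosis. A penetrance-model simulator of pure and heterogeneous
    epistatic case-control datasets, with tab-separated genotype file
    input/output, makes the whole pipeline reproducible without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
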