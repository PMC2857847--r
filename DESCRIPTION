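Package: gsprior
Title: Bayesian Whole-Genome Regression Methods for Genomic Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: MCMC samplers for four Bayesian whole-genome regression models
    used in genomic selection: SNP-BLUP with a common effect variance
    (Bayes BLUP), Bayes A with per-SNP scaled inverse-chi-squared variances,
    a Bayes A/B hybrid that runs reversible-jump variable selection every k
    Gibbs iterations, and Bayes C (stochastic search variable selection).
    All models include an optional pedigree polygenic term via the additive
    relationship matrix. The package also provides a gene-drop simulator of
    QTL-MAS-style datasets with known true breeding values, genomic breeding
    value (GEBV) prediction with linear extrapolation of time-series GEBV to
    an unobserved time point, and evaluation utilities (accuracy, mean squared
    error, top-rank overlap, and bias regression).
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    methods,
    stats,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
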