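Package: paracausal
Title: Causal Discovery of Secreted Stromal Regulators of Tumor Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers which secreted stromal genes causally drive expression
    changes in tumor cells from paired observational expression profiles, in a
    feedback-free conditioned-medium design. Provides a linear-Gaussian
    structural-equation simulator with planted paracrine regulators, an
    empirical-Bayes moderated-t differential expression stage with
    Benjamini-Hochberg correction and the candidate-gene selection cascade,
    PC-stable estimation of the stromal CPDAG with Fisher-z partial-correlation
    tests and Meek orientation, IDA intervention-calculus effect estimation
    under subsampling stability selection, and a Bayesian set-cover
    (model-based gene set analysis) condensation of stable effects into a
    sparse regulator list with known-positive calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    limma,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
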