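Package: hgtnet
Title: Horizontal Gene Transfer Network Inference from Match Length
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers networks of horizontal gene transfer (HGT) between
    bacterial taxa from the length distribution of maximal exact sequence
    matches (MLDs) shared by sets of genomes. Provides a suffix-array
    maximal exact match finder, log-binned per-comparison MLD statistics
    with a method-of-moments power-law exponent estimator, the analytic
    MLD model for continuous HGT (exponential single-event distributions,
    Laplace-transform relation, direct-transfer and hub-mediated power-law
    asymptotics with rank-1 transferability rates), joint network fitting
    with a trimmed log-residual objective, exponential-mixture fits for
    episodic transfer, and a sequence-level stochastic simulator that
    serves both as an oracle for the analytic model and as a synthetic
    data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
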