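Package: cellopt
Title: Cellulase Screening from Metagenomic Contigs and Classification of
    Enzyme Temperature and pH Optima
Version: 0.1.0
Authors@R:
    person("cellopt", "developers", email = "cellopt@example.org",
           role = c("aut", "cre"))
Description: Screens assembled metagenomic contigs for putative cellulase
    genes by six-frame translation and exact Smith-Waterman alignment
    against a reference cellulase set with Karlin-Altschul bit-score
    filtering, and classifies cellulase amino-acid sequences into optimum
    temperature (mesophilic, thermophilic, hyper-thermophilic) and optimum
    pH (acidic, neutral, alkaline) classes.  Classification uses a
    length-independent protein descriptor vector (amino-acid, dipeptide,
    grouped and pseudo amino-acid composition, CTD, conjoint triad,
    atom and bond composition), ANOVA F-test feature selection with
    Benjamini-Hochberg FDR control, SMOTE oversampling of minority
    classes, and a weighted soft-voting ensemble of a multilayer
    perceptron, a random forest, and a radial-basis-function support
    vector machine.  Includes a seeded synthetic-data generator and a
    leakage-safe repeated stratified cross-validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    quadprog,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
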