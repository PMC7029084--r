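Package: lhinvar
Title: Identification of Body-Size Invariant Life-History Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A five-criterion statistical framework for deciding whether
    life-history traits are invariant under body-size transformation.
    Implements median-normalized variance ratios, Hartigan's dip test with
    Monte-Carlo p-values and a two-standard-deviation coverage check (type I
    invariance), ordinary and phylogenetic generalized least-squares
    regression of log-transformed traits on body mass with Pagel's lambda
    estimated by maximum likelihood (type II invariance), and standardized
    major axis regression between trait pairs to flag isometry.  Includes a
    synthetic generator of pure-birth phylogenies and power-law trait data
    with known scaling exponents, phylogenetic signal, and missingness, so
    the full pipeline can be exercised against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    nlme,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
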