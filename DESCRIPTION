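Package: ctpoly
Title: Confined Polymer Models of Chromosome Territories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Coarse-grained bead-spring (Kremer-Grest) polymer simulations in
    spheroidal confinement, for studying how chromosome-territory shape and
    monomer density set the contact-probability scaling exponent. Provides a
    Langevin-dynamics engine (FENE bonds, WCA excluded volume, repulsive
    spheroid wall), trajectory observables (mean-squared internal distances,
    contact probability versus scaled contour separation, log-log scaling
    fits, normalized end-to-end distance distributions), an inverse
    shape-analysis pipeline (PCA spheroid fitting, sphericity, shape
    classification, cross-chromosome contact-curve normalization), synthetic
    ensemble generators, and XYZ/CMM/CSV/YAML input-output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
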