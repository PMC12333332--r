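Package: pepccs
Title: Collision Cross Sections and Structure Assignment for Gas-Phase
    Peptide Ions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ion-mobility mass-spectrometry (IM-MS) structure
    assignment of gas-phase peptide ions. Computes collision cross
    sections (CCS) from atomic geometries and partial charges with a
    trajectory-method engine (12-6 Lennard-Jones plus ion-induced-dipole
    potential, Monte-Carlo orientational averaging) and a
    projection-approximation engine; converts drift/arrival times to CCS
    via the low-field Mason-Schamp relation; reduces conformer ensembles
    by RMSD clustering with centroid extraction; forms Boltzmann-weighted
    ensemble CCS values under an energy window; and evaluates computed
    CCS against a packaged 23-peptide experimental reference set
    (percent error, success rate at a 3% threshold, dispersion-variant
    selection).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
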