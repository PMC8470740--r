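Package: idpens
Title: Conformational-Ensemble Analysis for Phosphorylated Disordered Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for conformational ensembles of intrinsically
    disordered peptides, with emphasis on phosphorylated sequences. Computes
    global size observables (radius of gyration, end-to-end distance) with
    autocorrelation and block-averaging error estimates, Debye-formula
    scattering curves with Guinier analysis, dimensionless Kratky plots and a
    chi-square fit against reference curves, residue contact maps and
    salt-bridge occupancies from a distance-angle hydrogen-bond criterion,
    Kabsch-Sander secondary-structure assignment extended with polyproline II
    detection, free-energy landscapes over principal components with Gaussian
    kernel density estimation and basin assignment, and sequence
    charge-patterning metrics (FCR, NCPR, kappa). Includes generators for
    synthetic ensembles (freely jointed chains, ideal-geometry backbones,
    planted contacts) so every stage can be validated against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
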