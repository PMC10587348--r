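Package: wsmel
Title: Wako-Saito-Munoz-Eaton Protein Folding Models with Virtual Linkers
Version: 0.1.0
Authors@R:
    person("Folding", "Models Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structure-based statistical mechanical models of protein folding
    in the Wako-Saito-Munoz-Eaton (WSME) family, extended with virtual linkers
    that let native contacts form between residues that are not connected by a
    fully native stretch of main chain (the WSME-L model), plus variants for
    oxidative disulfide-bond formation and for disulfide-intact folding.
    Provides exact transfer-matrix evaluation of partition functions
    restricted by one or two order parameters, an exhaustive-enumeration
    oracle for small chains, free-energy landscapes with basin, saddle and
    pathway analysis, theoretical Phi-value profiles, degree-of-disulfide
    formation, master-equation folding kinetics, thermodynamic scans, and a
    synthetic-fixture generator so that the whole stack can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
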