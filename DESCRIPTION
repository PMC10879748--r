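Package: quartetinv
Title: Detect Four-Node Hybridization Cycles from Quartet Concordance Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optimization-free detection of four-node hybridization cycles in
    level-1 phylogenetic networks under the multispecies coalescent. Builds the
    polynomial system of quartet concordance factors (CFs) implied by a candidate
    network, derives the phylogenetic invariants that true CFs must satisfy by
    eliminating branch-length and inheritance parameters, and ranks every
    candidate clade partition of a taxon set by the Euclidean norm of its
    evaluated invariants. Includes CF estimation from gene trees, a coalescent
    simulator on networks for validation, and a simulation suite with exact,
    Gaussian-perturbed, and multinomially sampled concordance factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
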