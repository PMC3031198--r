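Package: codiverge
Title: Hierarchical Approximate Bayesian Tests of Simultaneous Divergence
    and Migration Across Codistributed Taxon-Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative phylogeographic inference from multi-locus
    DNA sequence data sampled from multiple codistributed taxon-pairs.
    Implements a hierarchical approximate Bayesian computation (HABC)
    workflow: a structured-coalescent simulator for divergence with
    post-divergence migration and exponential population growth, finite-sites
    sequence evolution (JC, F81, HKY) with gamma rate heterogeneity across
    loci, moment-reduced and exchangeably sorted summary-statistic vectors,
    rejection sampling with local-linear and polychotomous regression
    adjustment, and a pseudo-observed data set (PODS) validation harness for
    estimator calibration and migration-model choice.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    nnet,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
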