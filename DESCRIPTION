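Package: mmcscan
Title: Selective Sweep Detection by Kingman Versus Multiple-Merger
    Coalescent Model Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A genomic scan for selective sweeps framed as coalescent model
    choice. A forward-in-time diploid Wright-Fisher simulator (with
    recombination, mutation, population bottlenecks, fixation-conditioned
    selective sweeps, and psi-sweepstakes reproduction episodes) generates
    training data under the Kingman and multiple-merger (psi) coalescent
    models. A panel of eleven site-frequency-spectrum, haplotype, and
    linkage-disequilibrium summary statistics is computed in sliding windows
    and each window is classified by rejection approximate Bayesian
    computation; windows whose posterior probability of the multiple-merger
    model exceeds a neutral 99% threshold are called sweep-like. Includes a
    leave-one-out cross-validation harness, a true/false-positive evaluation
    harness, ms-format input/output, and a small command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
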