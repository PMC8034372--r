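Package: decrange
Title: Ancestral Range Estimation on Chronograms with DEC-Family and
    Bayesian Binary Models
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Likelihood and Bayesian inference of ancestral geographic
    ranges on time-calibrated phylogenies.  Implements the
    dispersal-extinction-cladogenesis model family (DEC, DIVALIKE,
    BAYAREALIKE, each with an optional founder-event "+J" parameter) with
    maximum-likelihood fitting, AICc model comparison and nested
    likelihood-ratio tests, marginal ancestral-range reconstruction, and
    stochastic mapping of dispersal, vicariance and extinction events at
    focal nodes.  Also provides a Bayesian binary-character MCMC (BBM)
    reconstruction, gene-tree congruence filters for phylogenomic
    supermatrix construction (taxon-occupancy and Robinson-Foulds
    screening, third-codon-position stripping, partitioned
    concatenation), and simulators for Yule chronograms, range evolution
    with known histories, topologically discordant gene trees and codon
    alignments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
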