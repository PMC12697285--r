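Package: phyloburst
Title: Phylogenetic Coevolution of Transcriptional Burst Size and mRNA Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-gene transcriptional burst sizes, splicing rates and
    mRNA decay rates from spliced/unspliced single-cell count matrices under a
    bursty-transcription chemical master equation (with optional Poisson
    technical noise), and fits competing multivariate Ornstein-Uhlenbeck models
    of burst-size/decay-rate coevolution across a species phylogeny. The
    phylogenetic layer is a hierarchical mixture model: gene-specific optima
    are integrated out analytically under a Gaussian prior, and a white-noise
    component absorbs genes without phylogenetic signal. Competing constraint
    structures (decay-rate-constrained, burst-size-constrained, independent)
    are compared by AIC. A synthetic-data module simulates trait histories
    along a tree and count matrices from the bursty stationary law, so the
    whole pipeline can be validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
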