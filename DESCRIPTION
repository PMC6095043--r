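Package: lrnkit
Title: Local Regulatory Network Inference from Multi-Omic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers per-gene local regulatory networks (LRNs) from genotype,
    DNA methylation, histone acetylation, mRNA and phenotype data. Provides a
    linear-Gaussian synthetic-data generator with known causal structure,
    normalization and hidden-factor covariate removal, permutation-based
    cis-QTL and expression-epigenome association mapping with FDR control and
    Storey's pi1, constrained Bayesian-network structure MCMC with genetic
    variants as causal anchors (BGe scoring, new-edge-reversal moves, exact
    enumeration oracle), consensus-network construction, classification of
    epigenetic marks and genes as upstream, downstream or independent of
    expression and phenotypes, and the associated genomic-annotation and
    gene-set enrichment statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
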