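Package: coevo
Title: Phylogeny-Aware Clustering of Gene Presence/Absence Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects correlated evolution between binary phylogenetic
    profiles (gene presence/absence across genomes) with Pagel's
    likelihood-ratio test for discrete characters, turns the pairwise
    likelihood-ratio statistics into a distance matrix, clusters profiles
    by between-group average linkage (UPGMA), and evaluates clusterings
    functionally with Wang/G-SESAME Gene Ontology semantic similarity,
    resampling chi-squared enrichment tests with Benjamini-Hochberg
    correction, and exact binomial overrepresentation tests. Includes
    tree rooting utilities (midpoint and minimal ancestor deviation),
    profile construction from homology-search hit tables, and a
    continuous-time Markov chain simulator of binary traits on trees so
    the whole pipeline can be validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    phangorn,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    phytools,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
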