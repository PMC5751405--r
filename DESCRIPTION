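Package: tierbin
Title: Two-Tier Coverage and Composition Based Binning of Metagenomic Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised binning of assembled contigs from a single
    metagenomic sample. Contigs are first clustered in GC-log(coverage)
    space with a density-based (DBSCAN) step that detects outliers and
    infers the number of groups, then each coarse bin is refined in
    tetranucleotide-frequency space by principal component reduction
    followed by a Dirichlet-process Gaussian mixture model fitted with
    collapsed Gibbs sampling. Includes the standard binning evaluation
    measures (precision, recall, F1, species discovered) and a synthetic
    multi-strain community generator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
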