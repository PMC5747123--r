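Package: dotclust
Title: Ensemble-Guided RNA Structure Alignment and Motif Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise alignment of RNA sequences guided by their full
    secondary-structure ensembles (base-pair probability dot plots), using a
    partition function over probabilistic string alignments with stochastic
    backtracking, followed by unsupervised density-based clustering (OPTICS
    with xi-steepness extraction) to discover homologous RNA structure motifs.
    Includes a simplified thermodynamic folding engine, alignment- and
    cluster-quality metrics (MCC, SCI, ROC-AUC, cluster confusion), a
    structure-constrained synthetic family generator with dinucleotide-shuffled
    controls, and CLIP peak pre-processing utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    parallel,
    methods,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    generics,
    ggplot2,
    jsonlite,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
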