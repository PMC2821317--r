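Package: orthopair
Title: One-to-One Ortholog Assignment Between Closely Related Genomes by
    Rearrangement and Duplication Parsimony
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns one-to-one orthologs between two closely related annotated
    genomes by combining sequence similarity, Markov clustering of protein
    families, phylogenetic dating of tandem duplications, and parsimony
    minimisation of a rearrangement-plus-duplication (RD) distance. Tandemly
    arrayed inparalogs are identified on rooted per-family gene trees (codon
    alignments, F84 distances, BIONJ with an artificial outgroup) and removed
    before the rearrangement engine matches the remaining genes; a
    post-processing step recovers extra pairs from single-gene gaps inside
    collinear orthologous blocks. Includes a genome-evolution simulator with
    full ground truth, evaluation against simulated truth or gene-symbol
    benchmarks, and a benchmark harness, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    phangorn,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
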