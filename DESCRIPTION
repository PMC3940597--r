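Package: metaprof
Title: Taxonomic and Functional Profiling of Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for taxonomic and functional analysis of
    shotgun metagenomic samples. Extracts 16S/18S rRNA fragments from short
    reads with a profile hidden Markov model scanned on both strands, maps
    fragments to taxonomy-annotated reference databases with a k-mer seeded
    Smith-Waterman aligner, builds hierarchical abundance profiles from domain
    to species and integrates them across databases, compares samples with a
    Euclidean error-rate statistic and neighbor-joining phylogenies, predicts
    genes on assembled contigs and rolls their annotations up to GOSlim terms
    and a four-level SEED-style hierarchy, and exports interactive hierarchical
    visualizations as standalone SVG/HTML. Includes a read simulator with a
    per-base substitution error model and ground-truth tracking, plus fixture
    generators for reproducible end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    igraph,
    jsonlite,
    parallel,
    stats,
    utils,
    tools,
    grDevices,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2,
    withr
Config/testthat/edition: 3
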