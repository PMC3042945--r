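Package: gametotk
Title: Gametophyte Transcriptome Toolkit: Simulation, Assembly and
    Annotation Statistics for Normalized Long-Read cDNA Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested re-implementation of a classic de novo EST
    transcriptome characterization workflow for long single-end cDNA reads
    from a normalized library: read cleaning (adapter, polyA/T and length
    filters), two-step greedy overlap-layout-consensus assembly with
    retained singletons, sequence-set and assembly summary statistics, a
    bootstrapped unigene accumulation curve, best-hit and lowest-common-
    ancestor taxonomic screening from tabular homology hits, plastid
    genomic-DNA contamination flagging, perfect microsatellite (SSR)
    mining with flank checks, repeat-library screening, longest-ORF
    extraction, GO-slim mapping and Fisher-exact enrichment with FDR
    control, and conserved-gene detection rates. A seeded synthetic-data
    generator emulates a normalized 454-style read library with known
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
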