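Package: komapr
Title: Benchmarking Homology-Based Functional Annotation of Short Metagenomic Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmarking pipeline for translated-search functional
    annotation of short shotgun metagenomic reads against KEGG Orthology
    (KO) style gene catalogs. Simulates strided sliding-window reads with
    position-dependent substitution errors from annotated reference
    genomes, consumes BLAST outfmt-6 tabular alignments, applies four
    common read-annotation protocols (top gene, top KO, top-20 genes,
    top-20 KOs) with E-value/P-value fractional weighting, simulates
    incomplete reference databases by phylogenetic exclusion of
    alignments, and evaluates the results against ground truth with
    weighted precision/recall, single-copy-marker copy-number estimation,
    Jensen-Shannon profile distances, and pathway-level enrichment and
    differential-abundance analyses. A synthetic-community generator and
    oracle aligner provide fully controlled ground truth so the whole
    pipeline runs and is validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
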