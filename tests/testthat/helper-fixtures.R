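# Small shared fixture builders. Everything is constructed in code; no
# files ship with the tests.

toy_genome <- function(genome_id = "g1", n = 1000L,
                       genes = NULL, topology = "linear", seed = 1L) {
  if (is.null(genes)) {
    genes <- tibble::tibble(
      gene_id = c("g1.a", "g1.b"),
      start = c(101L, 501L), end = c(400L, 800L), strand = "+",
      ko_ids = c("K1", "")
    )
  }
  withr::with_seed(seed, genome_record(
    genome_id = genome_id,
    sequence = paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
    genes = genes,
    taxon = list(strain_id = genome_id, species_id = "spA", genus_id = "genA"),
    topology = topology
  ))
}

# A hit tibble row in the shape annotate_reads() consumes.
hit_row <- function(read_id, gene_id, evalue, bitscore = NULL) {
  tibble::tibble(
    read_id = read_id, gene_id = gene_id, pident = 90,
    length = 34L, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 101L,
    sstart = 1L, send = 34L, evalue = evalue,
    evalue_text = as.character(evalue),
    bitscore = bitscore %||% round(50 - 2 * log10(pmax(evalue, 1e-300)), 1),
    known_subject = TRUE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Catalog with two genomes across two genera for exclusion tests:
#   gSelf  (strain stA, species spA, genus genA) gene "self"  KO K1
#   gSib   (strain stB, species spA, genus genA) gene "sib"   KO K1
#   gCous  (strain stC, species spB, genus genA) gene "cous"  KO K1
#   gFar   (strain stD, species spC, genus genB) gene "far"   KO K2
nested_catalog <- function() {
  mk <- function(id, strain, species, genus, gene, ko) {
    genome_record(
      genome_id = id, sequence = strrep("ACGT", 200),
      genes = tibble::tibble(gene_id = gene, start = 101L, end = 400L,
                             strand = "+", ko_ids = ko),
      taxon = list(strain_id = strain, species_id = species,
                   genus_id = genus)
    )
  }
  build_catalog(list(
    mk("gSelf", "stA", "spA", "genA", "self", "K1"),
    mk("gSib", "stB", "spA", "genA", "sib", "K1"),
    mk("gCous", "stC", "spB", "genA", "cous", "K1"),
    mk("gFar", "stD", "spC", "genB", "far", "K2")
  ))
}

# Random small evaluation instance for oracle-equivalence checks: a tiny
# two-genome catalog, provenance rows, and a random hit table with
# frequent E-value ties.
random_instance <- function(seed) {
  withr::with_seed(seed, {
    n_genes <- sample(3:6, 1)
    kos <- paste0("K", 1:3)
    gene_ko <- sample(c(kos, "", ""), n_genes, replace = TRUE)
    starts <- 1L + (seq_len(n_genes) - 1L) * 500L + 100L
    genes <- tibble::tibble(
      gene_id = paste0("G", seq_len(n_genes)),
      start = starts, end = starts + 299L, strand = "+", ko_ids = gene_ko
    )
    gnm <- genome_record(
      genome_id = "rg", sequence = strrep("ACGT", (n_genes * 500 + 200) / 4),
      genes = genes,
      taxon = list(strain_id = "rg", species_id = "rs", genus_id = "rgn")
    )
    catalog <- build_catalog(list(gnm))
    n_reads <- sample(4:8, 1)
    # reads from random gene interiors plus one intergenic read
    src <- sample(seq_len(n_genes), n_reads - 1L, replace = TRUE)
    rstart <- genes$start[src] + sample(0:150, n_reads - 1L, replace = TRUE)
    rstart <- c(rstart, 10L)
    reads <- dplyr::bind_cols(
      tibble::tibble(read_id = paste0("r", seq_len(n_reads)),
                     genome_id = "rg", start = rstart, length = 101L),
      classify_position(gnm, rstart, 101L)
    )
    evs <- c(0, 1e-30, 1e-20, 1e-20, 1e-5, 0.5, 0.9)
    hits <- purrr::map_dfr(reads$read_id, function(r) {
      k <- sample(0:min(4L, n_genes), 1)
      if (k == 0) return(NULL)
      hit_row(r, sample(genes$gene_id, k), sample(evs, k, replace = TRUE))
    })
    hits <- if (nrow(hits)) sort_hits(hits) else hits
    list(reads = reads, hits = hits, catalog = catalog)
  })
}
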