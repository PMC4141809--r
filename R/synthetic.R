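#' Specify a synthetic community
#'
#' Describes a toy panel of annotated genomes with a nested taxonomy
#' (strains within species within genera) and shared gene families, so
#' that homology across taxonomic levels, single-copy markers, duplicated
#' KOs, non-KO genes and intergenic regions all exist by construction.
#' Gene family `f` is instantiated once in every genome (orthologs);
#' marker families are single copy everywhere. Generated KO ids are
#' `KM01..` for markers and `K0001..` for other KO families; non-KO
#' families have no KO. Sequence content is random nucleotide: homology
#' lives in the oracle's hit structure, not in sequence similarity.
#'
#' @param n_genera,n_species,n_strains Taxonomy shape: species per genus
#'   and strains per species.
#' @param genes_per_genome Gene families instantiated in each genome.
#' @param gene_length Gene length in bp (scalar, or `c(min, max)` for
#'   per-gene uniform draws).
#' @param fraction_ko Fraction of gene families carrying a KO
#'   (markers included).
#' @param intergenic_length Gap length between genes (scalar or range).
#' @param n_markers Number of universal single-copy marker KO families.
#' @param duplicated_kos Named integer vector, KO id -> copy number per
#'   genome (extra copies are appended to every genome).
#' @param n_pathways Pathways the KO families are spread over.
#' @param seed Required integer seed.
#' @return A `community_spec` list.
#' @export
community_spec <- function(n_genera = 2L, n_species = 2L, n_strains = 2L,
                           genes_per_genome = 30L, gene_length = 300L,
                           fraction_ko = 0.6, intergenic_length = 150L,
                           n_markers = 15L, duplicated_kos = NULL,
                           n_pathways = 4L, seed) {
  if (missing(seed)) stop("community_spec requires a seed")
  stopifnot(fraction_ko >= 0, fraction_ko <= 1,
            n_markers <= ceiling(fraction_ko * genes_per_genome))
  if (!is.null(duplicated_kos) &&
      (is.null(names(duplicated_kos)) || any(duplicated_kos < 1)))
    stop("duplicated_kos must be a named vector of copy numbers >= 1")
  structure(list(n_genera = n_genera, n_species = n_species,
                 n_strains = n_strains,
                 genes_per_genome = genes_per_genome,
                 gene_length = gene_length, fraction_ko = fraction_ko,
                 intergenic_length = intergenic_length,
                 n_markers = n_markers,
                 duplicated_kos = duplicated_kos,
                 n_pathways = n_pathways, seed = as.integer(seed)),
            class = "community_spec")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

draw_len <- function(len) {
  if (length(len) == 2L) sample(seq.int(len[1], len[2]), 1L) else as.integer(len)
}

#' Build a synthetic annotated community
#'
#' Deterministic under the spec's seed: produces the genome records, the
#' KO catalog (with a `family_id` column the oracle aligner uses), and a
#' KO-to-pathway membership table.
#'
#' @param spec A [community_spec()].
#' @return List with `genomes` (named list of `genome_record`s),
#'   `catalog` (`ko_catalog`), `pathways` (tibble), `markers` (character
#'   vector of marker KO ids), and `spec`.
#' @export
build_community <- function(spec) {
  s <- spec
  n_fam <- s$genes_per_genome
  n_ko_fam <- ceiling(s$fraction_ko * n_fam)
  markers <- if (s$n_markers > 0) sprintf("KM%02d", seq_len(s$n_markers))
             else character(0)
  other_ko <- if (n_ko_fam > s$n_markers)
    sprintf("K%04d", seq_len(n_ko_fam - s$n_markers)) else character(0)
  fam_ko <- c(markers, other_ko, rep("", n_fam - n_ko_fam))
  fam_id <- sprintf("F%03d", seq_len(n_fam))

  extra <- NULL
  if (!is.null(s$duplicated_kos)) {
    miss <- setdiff(names(s$duplicated_kos), fam_ko)
    if (length(miss)) stop("duplicated_kos reference unknown KO ids: ",
                           paste(miss, collapse = ", "))
    extra <- purrr::imap_dfr(as.list(s$duplicated_kos), function(cn, ko) {
      f <- fam_id[match(ko, fam_ko)]
      if (cn > 1) tibble(family_id = f, ko_id = ko, copy = 2:cn)
      else tibble(family_id = character(), ko_id = character(),
                  copy = integer())
    })
  }
  genome_ids <- expand.grid(st = seq_len(s$n_strains),
                            sp = seq_len(s$n_species),
                            ge = seq_len(s$n_genera))

  genomes <- withr::with_seed(s$seed, {
    purrr::pmap(genome_ids, function(st, sp, ge) {
      genus <- sprintf("gen%d", ge)
      species <- sprintf("gen%d.sp%d", ge, sp)
      strain <- sprintf("gen%d.sp%d.st%d", ge, sp, st)
      fams <- tibble(family_id = fam_id, ko_id = fam_ko, copy = 1L)
      if (!is.null(extra) && nrow(extra)) {
        fams <- dplyr::bind_rows(fams, extra)
      }
      pos <- 1L
      rows <- vector("list", nrow(fams))
      seq_parts <- character(2L * nrow(fams) + 1L)
      for (i in seq_len(nrow(fams))) {
        ig <- draw_len(s$intergenic_length)
        gl <- draw_len(s$gene_length)
        seq_parts[2L * i - 1L] <- random_dna(ig)
        seq_parts[2L * i] <- random_dna(gl)
        start <- pos + ig
        rows[[i]] <- tibble(
          gene_id = sprintf("%s|%s.%d", strain, fams$family_id[i],
                            fams$copy[i]),
          start = start, end = start + gl - 1L, strand = "+",
          ko_ids = fams$ko_id[i], family_id = fams$family_id[i])
        pos <- start + gl
      }
      seq_parts[2L * nrow(fams) + 1L] <- random_dna(draw_len(s$intergenic_length))
      genome_record(
        genome_id = strain,
        sequence = paste(seq_parts, collapse = ""),
        genes = dplyr::bind_rows(rows),
        taxon = list(strain_id = strain, species_id = species,
                     genus_id = genus)
      )
    })
  })
  names(genomes) <- vapply(genomes, `[[`, character(1), "genome_id")

  kos <- c(markers, other_ko)
  pathways <- if (length(kos) && s$n_pathways > 0) {
    pw <- sprintf("path%02d", (seq_along(kos) - 1L) %% s$n_pathways + 1L)
    second <- seq_along(kos) %% 3L == 0L
    dplyr::bind_rows(
      tibble(ko_id = kos, pathway_id = pw),
      tibble(ko_id = kos[second],
             pathway_id = sprintf("path%02d",
                                  seq_along(kos)[second] %% s$n_pathways + 1L))
    ) |>
      dplyr::distinct() |>
      dplyr::arrange(.data$ko_id, .data$pathway_id)
  } else tibble(ko_id = character(), pathway_id = character())

  catalog <- build_catalog(genomes, pathways)
  # by construction no sequence similarity crosses families
  attr(catalog, "cross_ko_similarity") <-
    stats::setNames(rep(0, length(kos)), kos)
  list(genomes = genomes, catalog = catalog, pathways = pathways,
       markers = markers, spec = s)
}

#' Specify an oracle aligner
#'
#' The oracle stands in for a translated search against a reference
#' database: every read from a gene receives a self hit, hits to its
#' family's homologs at E-values set by the taxonomic relationship, and
#' optionally a cross-family "remote" hit (different KO, different
#' genus) plus random decoy hits. With probability `corruption_rate` a
#' gene read's self hit is dropped, modelling mappability failure.
#'
#' @param self_evalue E-value of the self hit.
#' @param homolog_evalues Named numeric vector with any of `strain`
#'   (paralogous extra copies in the same genome), `species` (sibling
#'   strains), `genus` (other species in the genus). `NULL` disables
#'   homolog hits entirely.
#' @param remote_evalue E-value of a deterministic cross-family hit in a
#'   different genus (`NULL`, the default, disables it).
#' @param decoy_rate Probability a read receives one random decoy hit.
#' @param decoy_evalue_range E-value range for decoy hits.
#' @param corruption_rate Probability a gene read's self hit is dropped.
#' @param seed Required integer seed.
#' @return An `oracle_spec` list.
#' @export
oracle_spec <- function(self_evalue = 1e-40,
                        homolog_evalues = c(strain = 1e-35,
                                            species = 1e-20,
                                            genus = 1e-10),
                        remote_evalue = NULL,
                        decoy_rate = 0, decoy_evalue_range = c(0.01, 0.9),
                        corruption_rate = 0, seed) {
  if (missing(seed)) stop("oracle_spec requires a seed")
  stopifnot(decoy_rate >= 0, decoy_rate <= 1,
            corruption_rate >= 0, corruption_rate <= 1)
  hvals <- c(homolog_evalues, remote_evalue)
  if (length(hvals) && (any(self_evalue > hvals) ||
                        any(hvals > decoy_evalue_range[1]))) {
    stop("E-values must be ordered: self <= homolog/remote <= decoy range")
  }
  structure(list(self_evalue = self_evalue,
                 homolog_evalues = homolog_evalues,
                 remote_evalue = remote_evalue,
                 decoy_rate = decoy_rate,
                 decoy_evalue_range = decoy_evalue_range,
                 corruption_rate = corruption_rate,
                 seed = as.integer(seed)),
            class = "oracle_spec")
}

format_evalue <- function(e) {
  vapply(e, function(x) format(signif(x, 3), scientific = x < 1e-3),
         character(1))
}

oracle_hit_rows <- function(read_id, gene_id, evalue, pident, L) {
  aa <- as.integer(ceiling(L / 3))
  tibble(
    read_id = read_id, gene_id = gene_id, pident = pident,
    length = aa, mismatch = 0L, gapopen = 0L, qstart = 1L, qend = L,
    sstart = 1L, send = aa,
    evalue = evalue, evalue_text = format_evalue(evalue),
    bitscore = round(50 - 2 * log10(pmax(evalue, 1e-300)), 1),
    known_subject = TRUE
  )
}

#' Run the oracle aligner on a set of simulated reads
#'
#' Produces a hit table in the same shape as [parse_hits()] output (and
#' writable with [write_hits()]), deterministic under the oracle seed.
#' Reads fully contained in a gene receive the self/homolog/remote hit
#' structure; intergenic and boundary-spanning reads receive only decoy
#' hits.
#'
#' @param reads Read tibble from [generate_reads()] over community
#'   genomes.
#' @param community Output of [build_community()] (or any list with a
#'   `catalog` whose gene table has a `family_id` column).
#' @param spec An [oracle_spec()].
#' @return Hit tibble in canonical order.
#' @export
oracle_align <- function(reads, community, spec) {
  genes <- community$catalog$genes
  if (!"family_id" %in% names(genes)) {
    stop("community catalog lacks a family_id column")
  }
  L <- unique(reads$length)
  stopifnot(length(L) == 1L)

  gene_reads <- reads |>
    dplyr::filter(!is.na(.data$source_gene)) |>
    dplyr::mutate(source_gene_1 =
                    vapply(split_ids(.data$source_gene), `[`, character(1), 1))
  src <- genes[match(gene_reads$source_gene_1, genes$gene_id), ]

  withr::with_seed(spec$seed, {
    corrupted <- stats::runif(nrow(gene_reads)) < spec$corruption_rate

    self_hits <- oracle_hit_rows(
      gene_reads$read_id[!corrupted], gene_reads$source_gene_1[!corrupted],
      rep(spec$self_evalue, sum(!corrupted)), 98, L)

    hom_hits <- NULL
    if (length(spec$homolog_evalues)) {
      fam <- dplyr::select(genes, member_gene = "gene_id",
                           "family_id", member_genome = "genome_id",
                           member_species = "species_id",
                           member_genus = "genus_id")
      pairs <- tibble(read_id = gene_reads$read_id,
                      source_gene_1 = gene_reads$source_gene_1,
                      family_id = src$family_id,
                      genome_id = src$genome_id,
                      species_id = src$species_id,
                      genus_id = src$genus_id) |>
        dplyr::inner_join(fam, by = "family_id",
                          relationship = "many-to-many") |>
        dplyr::filter(.data$member_gene != .data$source_gene_1) |>
        dplyr::mutate(level = dplyr::case_when(
          .data$member_genome == .data$genome_id ~ "strain",
          .data$member_species == .data$species_id ~ "species",
          .data$member_genus == .data$genus_id ~ "genus",
          TRUE ~ "other_genus"
        )) |>
        dplyr::filter(.data$level %in% names(spec$homolog_evalues))
      if (nrow(pairs)) {
        ident <- c(strain = 96, species = 88, genus = 75)
        hom_hits <- oracle_hit_rows(
          pairs$read_id, pairs$member_gene,
          unname(spec$homolog_evalues[pairs$level]),
          unname(ident[pairs$level]), L)
      }
    }

    remote_hits <- NULL
    if (!is.null(spec$remote_evalue)) {
      # deterministic cross-family partner: the next KO-bearing family in
      # a genome from another genus (different KO by construction)
      ko_fams <- genes |>
        dplyr::filter(nzchar(.data$ko_ids)) |>
        dplyr::distinct(.data$family_id) |>
        dplyr::arrange(.data$family_id) |>
        dplyr::pull()
      partner_fam <- function(f) {
        cand <- setdiff(ko_fams, f)
        cand[(match(f, sort(unique(genes$family_id))) - 1L) %%
               length(cand) + 1L]
      }
      pf <- vapply(src$family_id, partner_fam, character(1))
      partner_gene <- vapply(seq_along(pf), function(i) {
        g <- genes[genes$family_id == pf[i] &
                     genes$genus_id != src$genus_id[i], ]
        if (!nrow(g)) NA_character_ else g$gene_id[order(g$gene_id)][1]
      }, character(1))
      ok <- !is.na(partner_gene)
      if (any(ok)) {
        remote_hits <- oracle_hit_rows(
          gene_reads$read_id[ok], partner_gene[ok],
          rep(spec$remote_evalue, sum(ok)), 55, L)
      }
    }

    decoy_hits <- NULL
    if (spec$decoy_rate > 0) {
      gets <- stats::runif(nrow(reads)) < spec$decoy_rate
      idx <- which(gets)
      if (length(idx)) {
        src_fam <- genes$family_id[match(
          vapply(split_ids(reads$source_gene[idx]), function(x)
            if (length(x)) x[1] else NA_character_, character(1)),
          genes$gene_id)]
        decoy_gene <- vapply(seq_along(idx), function(i) {
          cand <- genes$gene_id[is.na(src_fam[i]) |
                                  genes$family_id != src_fam[i]]
          sample(cand, 1L)
        }, character(1))
        ev <- stats::runif(length(idx), spec$decoy_evalue_range[1],
                           spec$decoy_evalue_range[2])
        decoy_hits <- oracle_hit_rows(reads$read_id[idx], decoy_gene,
                                      signif(ev, 3), 40, L)
      }
    }
    out <- dplyr::bind_rows(self_hits, hom_hits, remote_hits, decoy_hits)
  })
  sort_hits(out)
}

#' Bundled worked fixtures
#'
#' Two tiny hand-worked cases used throughout the test suite:
#' \describe{
#'   \item{F1}{Three reads (one from a KO gene, one from a non-KO gene
#'     with a worse KO-bearing alignment, one intergenic with a KO hit).
#'     Under `top_gene`, KO precision is exactly 0.5 and KO recall 1;
#'     under `top_ko` precision is exactly 1/3.}
#'   \item{F2}{A single genome with three single-copy marker KOs and one
#'     KO present in two copies, all genes 300 bp; under step-1 reads
#'     and a perfect oracle, the duplicated KO's estimated copy number
#'     is exactly 2.}
#' }
#'
#' @return List with elements `F1` and `F2`, each carrying `reads`,
#'   `hits`, `catalog`, plus `markers`/`genome` where relevant, and the
#'   `expected` values.
#' @export
worked_fixtures <- function() {
  ## ---- F1: three-read evaluation case ----
  f1_ga <- genome_record(
    genome_id = "F1a",
    sequence = strrep("ACGT", 300),  # 1200 bp
    genes = tibble(gene_id = c("gKO", "gNON"),
                   start = c(101L, 501L), end = c(400L, 800L),
                   strand = "+", ko_ids = c("K1", "")),
    taxon = list(strain_id = "F1a", species_id = "f1.spA", genus_id = "f1")
  )
  f1_gb <- genome_record(
    genome_id = "F1b",
    sequence = strrep("TGCA", 150),  # 600 bp
    genes = tibble(gene_id = "gK2", start = 101L, end = 400L,
                   strand = "+", ko_ids = "K2"),
    taxon = list(strain_id = "F1b", species_id = "f1.spB", genus_id = "f1")
  )
  f1_catalog <- build_catalog(list(f1_ga, f1_gb))
  f1_reads <- dplyr::bind_rows(
    dplyr::mutate(classify_intervals(f1_ga, c(150L, 550L, 900L), 101L),
                  read_id = c("r1", "r2", "r3"), genome_id = "F1a",
                  start = c(150L, 550L, 900L), length = 101L,
                  .before = 1),
  )
  f1_hits <- dplyr::bind_rows(
    oracle_hit_rows("r1", "gKO", 1e-30, 98, 101L),
    oracle_hit_rows("r2", "gNON", 1e-20, 98, 101L),
    oracle_hit_rows("r2", "gK2", 0.5, 60, 101L),
    oracle_hit_rows("r3", "gK2", 0.1, 60, 101L)
  ) |>
    sort_hits()

  ## ---- F2: equal-length copy-number case ----
  lay <- tibble(
    gene_id = c("m1", "m2", "m3", "dup.1", "dup.2"),
    ko_ids = c("FM1", "FM2", "FM3", "FDUP", "FDUP"),
    family_id = c("FM1", "FM2", "FM3", "FDUP", "FDUP")
  )
  gl <- 300L; ig <- 150L
  starts <- ig + 1L + (seq_len(nrow(lay)) - 1L) * (gl + ig)
  f2_genes <- dplyr::mutate(lay, start = starts, end = starts + gl - 1L,
                            strand = "+")
  f2_len <- max(f2_genes$end) + ig
  f2_genome <- withr::with_seed(7L, genome_record(
    genome_id = "F2g", sequence = random_dna(f2_len),
    genes = f2_genes,
    taxon = list(strain_id = "F2g", species_id = "f2.sp", genus_id = "f2")
  ))
  f2_catalog <- build_catalog(list(f2_genome))
  f2_reads <- generate_reads(f2_genome, read_length = 101L, step = 1L)
  f2_comm <- list(catalog = f2_catalog)
  f2_hits <- oracle_align(f2_reads, f2_comm,
                          oracle_spec(homolog_evalues = NULL, seed = 7L))

  list(
    F1 = list(reads = f1_reads, hits = f1_hits, catalog = f1_catalog,
              genomes = list(f1_ga, f1_gb),
              expected = list(top_gene = list(precision_ko = 0.5,
                                              recall_ko = 1.0),
                              top_ko = list(precision_ko = 1 / 3,
                                            recall_ko = 1.0))),
    F2 = list(reads = f2_reads, hits = f2_hits, catalog = f2_catalog,
              genome = f2_genome, markers = c("FM1", "FM2", "FM3"),
              expected = list(copy_number = list(FDUP = 2.0, FM1 = 1.0,
                                                 FM2 = 1.0, FM3 = 1.0)))
  )
}
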