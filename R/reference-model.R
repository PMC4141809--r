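#' @importFrom rlang .data .env %||%
#' @importFrom tibble tibble as_tibble
NULL

ORIGIN_LEVELS <- c("KO_GENE", "NON_KO_GENE", "INTERGENIC", "MULTI")

#' Construct a genome record
#'
#' A genome record couples a nucleotide sequence with its gene table and
#' taxonomic lineage. Gene coordinates are 1-based inclusive; internal
#' window arithmetic is 0-based half-open. Overlapping genes are permitted:
#' a position covered by at least one KO-annotated gene is labelled
#' `KO_GENE`, any other gene-covered position `NON_KO_GENE`.
#'
#' @param genome_id Genome identifier.
#' @param sequence Nucleotide sequence as a single string (ACGT).
#' @param genes Tibble with columns `gene_id`, `start`, `end`, `strand`,
#'   `ko_ids` (comma-separated string, may be empty).
#' @param taxon Named list or one-row data frame with `strain_id`,
#'   `species_id`, `genus_id`.
#' @param topology `"linear"` (default) or `"circular"`. Circular genomes
#'   wrap read windows past the origin.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, sequence, genes, taxon,
                          topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  genes <- as_tibble(genes)
  if (!"ko_ids" %in% names(genes)) genes$ko_ids <- ""
  genes$ko_ids[is.na(genes$ko_ids)] <- ""
  if (!"strand" %in% names(genes)) genes$strand <- "+"
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  glen <- nchar(sequence)
  bad <- !(genes$start >= 1L & genes$start <= genes$end & genes$end <= glen)
  if (any(bad)) {
    stop("invalid coordinates for gene(s): ",
         paste(genes$gene_id[bad], collapse = ", "),
         " (genome ", genome_id, ", length ", glen, ")")
  }
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in genome ", genome_id, ": ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  taxon <- as.list(taxon)[c("strain_id", "species_id", "genus_id")]
  if (any(vapply(taxon, function(x) is.null(x) || !nzchar(x), logical(1)))) {
    stop("taxon for genome ", genome_id,
         " must have non-empty strain_id, species_id and genus_id")
  }
  structure(
    list(genome_id = genome_id, sequence = sequence, genes = genes,
         taxon = taxon, topology = topology),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$genome_id, ": ", nchar(x$sequence), " bp, ",
      nrow(x$genes), " genes (", sum(gene_has_ko(x$genes)), " KO), ",
      x$topology, "\n", sep = "")
  invisible(x)
}

gene_has_ko <- function(genes) nzchar(trimws(genes$ko_ids))

split_kos <- function(ko_ids) {
  lapply(strsplit(ko_ids, ","), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
}

#' Read a genome from FASTA plus a gene table
#'
#' The gene table is tab-separated with columns `gene_id`, `genome_id`,
#' `start`, `end`, `strand`, `ko_ids`, `strain_id`, `species_id`,
#' `genus_id`. The FASTA file must contain exactly one record whose name
#' matches the table's `genome_id`.
#'
#' @param sequence_path Path to a single-record nucleotide FASTA.
#' @param annotation_path Path to the tab-separated gene table.
#' @param topology Passed to [genome_record()].
#' @return A `genome_record`.
#' @export
read_genome <- function(sequence_path, annotation_path,
                        topology = c("linear", "circular")) {
  seqs <- Biostrings::readDNAStringSet(sequence_path)
  tab <- readr::read_tsv(annotation_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           gene_id = "c", genome_id = "c", start = "i",
                           end = "i", strand = "c", ko_ids = "c",
                           strain_id = "c", species_id = "c", genus_id = "c"
                         ))
  gid <- unique(tab$genome_id)
  if (length(gid) != 1L) stop("gene table references multiple genome_ids")
  nm <- sub("\\s.*$", "", names(seqs))
  if (!gid %in% nm) stop("FASTA has no record named ", gid)
  if (sum(nm == gid) != 1L) stop("FASTA has multiple records named ", gid)
  tab$ko_ids[is.na(tab$ko_ids)] <- ""
  genome_record(
    genome_id = gid,
    sequence = as.character(seqs[[which(nm == gid)]]),
    genes = tab[, c("gene_id", "start", "end", "strand", "ko_ids")],
    taxon = list(strain_id = tab$strain_id[1], species_id = tab$species_id[1],
                 genus_id = tab$genus_id[1]),
    topology = topology
  )
}

#' Write a genome record back to FASTA + gene table
#'
#' @param genome A `genome_record`.
#' @param sequence_path,annotation_path Output paths.
#' @return `genome`, invisibly.
#' @export
write_genome <- function(genome, sequence_path, annotation_path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$genome_id
  Biostrings::writeXStringSet(ss, sequence_path, width = 70L)
  tab <- dplyr::mutate(genome$genes,
                       genome_id = genome$genome_id,
                       strain_id = genome$taxon$strain_id,
                       species_id = genome$taxon$species_id,
                       genus_id = genome$taxon$genus_id,
                       .after = "gene_id")
  readr::write_tsv(tab, annotation_path)
  invisible(genome)
}

# Per-base origin category of a genome as an integer vector over positions
# 1..G: 1 = KO gene, 2 = non-KO gene, 3 = intergenic. KO coverage dominates
# overlapping annotations.
base_categories <- function(genome) {
  G <- nchar(genome$sequence)
  cat <- rep.int(3L, G)
  genes <- genome$genes
  if (nrow(genes)) {
    has_ko <- gene_has_ko(genes)
    # KO coverage dominates, so paint non-KO genes first
    for (i in which(!has_ko)) cat[genes$start[i]:genes$end[i]] <- 2L
    for (i in which(has_ko)) cat[genes$start[i]:genes$end[i]] <- 1L
  }
  cat
}

wrap_positions <- function(pos, G) ((pos - 1L) %% G) + 1L

#' Classify the origin category of a genomic interval
#'
#' Labels the interval `[start, start + length - 1]` as originating from a
#' KO-annotated gene, a gene without KO annotation, an intergenic region,
#' or `MULTI` if it spans more than one category. Overlap fractions over
#' the three base categories always sum to 1.
#'
#' @param genome A `genome_record`.
#' @param start 1-based start coordinate.
#' @param length Interval length in bp.
#' @return One-row tibble with `origin`, `gene_ids` (comma-separated ids of
#'   overlapped genes), `source_gene` (gene fully containing the interval,
#'   if any), `frac_ko`, `frac_non_ko`, `frac_intergenic`.
#' @export
classify_position <- function(genome, start, length) {
  classify_intervals(genome, start, length)
}

# Vectorised interval classification; `start` may be a vector.
classify_intervals <- function(genome, start, length) {
  G <- nchar(genome$sequence)
  start <- as.integer(start)
  L <- as.integer(length)
  if (genome$topology == "linear" &&
      any(start < 1L | start + L - 1L > G)) {
    stop("interval outside linear genome of length ", G)
  }
  cat <- base_categories(genome)
  if (genome$topology == "circular") cat <- c(cat, cat[seq_len(min(L - 1L, G))])
  cums <- cbind(ko = cumsum(cat == 1L), nk = cumsum(cat == 2L),
                ig = cumsum(cat == 3L))
  lo <- start
  hi <- start + L - 1L
  cnt <- cums[hi, , drop = FALSE] -
    rbind(c(0, 0, 0), cums, deparse.level = 0)[lo, , drop = FALSE]
  frac <- cnt / L

  genes <- genome$genes
  gene_hits <- rep("", length(start))
  src <- rep(NA_character_, length(start))
  src_kos <- rep("", length(start))
  if (nrow(genes)) {
    q <- IRanges::IRanges(start = lo, end = hi)
    s <- IRanges::IRanges(start = genes$start, end = genes$end)
    if (genome$topology == "circular") {
      # wrapped tail maps back to the genome head
      s <- c(s, IRanges::IRanges(start = genes$start + G, end = genes$end + G))
    }
    ov <- IRanges::findOverlaps(q, s)
    qh_raw <- S4Vectors::queryHits(ov)
    sh_raw <- S4Vectors::subjectHits(ov)
    gene_idx <- (sh_raw - 1L) %% nrow(genes) + 1L
    contained_raw <- IRanges::start(s)[sh_raw] <= lo[qh_raw] &
      IRanges::end(s)[sh_raw] >= hi[qh_raw]
    keep <- !duplicated(paste(qh_raw, gene_idx))
    qh <- qh_raw[keep]
    sh <- gene_idx[keep]
    if (length(qh)) {
      gene_hits <- vapply(split(genes$gene_id[sh], factor(qh, seq_along(start))),
                          function(g) paste(sort(unique(g)), collapse = ","),
                          character(1))
      cok <- contained_raw
      if (any(cok)) {
        cg <- split(gene_idx[cok], factor(qh_raw[cok], seq_along(start)))
        src <- vapply(cg, function(i) {
          if (!length(i)) return(NA_character_)
          paste(sort(unique(genes$gene_id[i])), collapse = ",")
        }, character(1))
        src_kos <- vapply(cg, function(i) {
          if (!length(i)) return("")
          kos <- unlist(split_kos(genes$ko_ids[i]))
          paste(sort(unique(kos)), collapse = ",")
        }, character(1))
      }
    }
  }
  n_cat <- rowSums(cnt > 0L)
  origin <- dplyr::case_when(
    n_cat > 1L ~ "MULTI",
    cnt[, "ko"] == L ~ "KO_GENE",
    cnt[, "nk"] == L ~ "NON_KO_GENE",
    TRUE ~ "INTERGENIC"
  )
  tibble(
    origin = origin,
    gene_ids = unname(gene_hits),
    source_gene = unname(src),
    source_kos = unname(src_kos),
    frac_ko = unname(frac[, "ko"]),
    frac_non_ko = unname(frac[, "nk"]),
    frac_intergenic = unname(frac[, "ig"])
  )
}

#' Build a KO catalog from genome records
#'
#' Collects every gene's length, KO membership and taxonomy into the
#' lookup tables the annotation and profile layers consult, together with
#' an optional KO-to-pathway membership table.
#'
#' @param genomes A list of `genome_record` objects (or a single one).
#' @param pathways Optional tibble with columns `ko_id`, `pathway_id`.
#' @return An object of class `ko_catalog` with tibbles `genes` (gene_id,
#'   genome_id, length, ko_ids, strain/species/genus ids), `ko_genes`
#'   (long ko_id–gene_id pairs) and `ko_pathways`.
#' @export
build_catalog <- function(genomes, pathways = NULL) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  if (!length(genomes)) stop("genome list is empty")
  genes <- purrr::map_dfr(genomes, function(g) {
    dplyr::mutate(g$genes,
                  genome_id = g$genome_id,
                  length = .data$end - .data$start + 1L,
                  strain_id = g$taxon$strain_id,
                  species_id = g$taxon$species_id,
                  genus_id = g$taxon$genus_id)
  })
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) {
    conf <- genes |>
      dplyr::filter(.data$gene_id %in% dup) |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::summarise(n = dplyr::n_distinct(.data$length), .groups = "drop")
    if (any(conf$n > 1L)) {
      stop("conflicting lengths for repeated gene_id: ",
           paste(conf$gene_id[conf$n > 1L], collapse = ", "))
    }
    genes <- genes[!duplicated(genes$gene_id), ]
  }
  ko_genes <- genes |>
    dplyr::select("gene_id", "ko_ids") |>
    dplyr::mutate(ko_id = split_kos(.data$ko_ids)) |>
    tidyr::unnest("ko_id") |>
    dplyr::select("ko_id", "gene_id") |>
    dplyr::arrange(.data$ko_id, .data$gene_id)
  if (is.null(pathways)) {
    pathways <- tibble(ko_id = character(), pathway_id = character())
  }
  keep <- c("gene_id", "genome_id", "length", "ko_ids",
            "strain_id", "species_id", "genus_id")
  extra <- setdiff(names(genes), c(keep, "start", "end", "strand"))
  structure(
    list(genes = genes[, c(keep, extra)],
         ko_genes = ko_genes,
         ko_pathways = as_tibble(pathways)),
    class = "ko_catalog"
  )
}

#' @export
print.ko_catalog <- function(x, ...) {
  cat("<ko_catalog> ", nrow(x$genes), " genes, ",
      dplyr::n_distinct(x$ko_genes$ko_id), " KOs, ",
      dplyr::n_distinct(x$genes$genome_id), " genomes, ",
      dplyr::n_distinct(x$ko_pathways$pathway_id), " pathways\n", sep = "")
  invisible(x)
}

#' KO ids present in a catalog
#'
#' @param catalog A `ko_catalog`.
#' @return Character vector of KO ids.
#' @export
catalog_kos <- function(catalog) unique(catalog$ko_genes$ko_id)

# gene_id -> character vector of KO ids (possibly empty)
gene_ko_map <- function(catalog) {
  m <- split_kos(catalog$genes$ko_ids)
  names(m) <- catalog$genes$gene_id
  m
}

#' Serialize a catalog to tab-separated files
#'
#' Writes the gene table and the KO-to-pathway table; [read_catalog()]
#' round-trips them losslessly.
#'
#' @param catalog A `ko_catalog`.
#' @param genes_path,pathways_path Output paths (pathways optional).
#' @return `catalog`, invisibly.
#' @export
write_catalog <- function(catalog, genes_path, pathways_path = NULL) {
  readr::write_tsv(catalog$genes, genes_path)
  if (!is.null(pathways_path)) {
    readr::write_tsv(catalog$ko_pathways, pathways_path)
  }
  invisible(catalog)
}

#' Read a catalog written by [write_catalog()]
#'
#' @param genes_path,pathways_path Paths written by [write_catalog()].
#' @return A `ko_catalog`.
#' @export
read_catalog <- function(genes_path, pathways_path = NULL) {
  genes <- readr::read_tsv(genes_path, show_col_types = FALSE,
                           col_types = readr::cols(
                             gene_id = "c", genome_id = "c", length = "i",
                             ko_ids = "c", strain_id = "c",
                             species_id = "c", genus_id = "c",
                             .default = readr::col_guess()
                           ))
  genes$ko_ids[is.na(genes$ko_ids)] <- ""
  pathways <- if (is.null(pathways_path)) NULL else {
    readr::read_tsv(pathways_path, show_col_types = FALSE,
                    col_types = "cc")
  }
  ko_genes <- genes |>
    dplyr::select("gene_id", "ko_ids") |>
    dplyr::mutate(ko_id = split_kos(.data$ko_ids)) |>
    tidyr::unnest("ko_id") |>
    dplyr::select("ko_id", "gene_id") |>
    dplyr::arrange(.data$ko_id, .data$gene_id)
  structure(
    list(genes = genes,
         ko_genes = ko_genes,
         ko_pathways = pathways %||%
           tibble(ko_id = character(), pathway_id = character())),
    class = "ko_catalog"
  )
}

#' Read a two-column KO-to-pathway membership table
#'
#' @param path TSV with columns `ko_id`, `pathway_id`.
#' @return A tibble.
#' @export
read_pathways <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, col_types = "cc")
}
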