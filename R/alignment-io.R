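OUTFMT6_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                  "gapopen", "qstart", "qend", "sstart", "send",
                  "evalue", "bitscore")

#' Parse a translated-search tabular alignment file
#'
#' Reads a 12-column BLAST outfmt-6 table, discards hits at or above the
#' E-value cutoff (strict `<`, the HMP convention with cutoff 1), and
#' sorts the hits for each read into the canonical order: ascending
#' E-value, ties broken by descending bitscore, then lexicographic subject
#' gene id. E-value ties are defined on the decimal string as printed by
#' the aligner (`evalue_text`), since printed precision is coarser than
#' the float round-trip.
#'
#' @param path Path to a tab-separated 12-column alignment file.
#' @param catalog Optional `ko_catalog`; subjects absent from it are
#'   flagged (`known_subject = FALSE`) or rejected.
#' @param evalue_cutoff Retain hits with E-value strictly below this
#'   (default 1).
#' @param unknown_subject `"flag"` (default) or `"error"`.
#' @return Tibble of hits with the outfmt-6 columns (`sseqid` renamed
#'   `gene_id`, `qseqid` renamed `read_id`), plus `evalue_text` and
#'   `known_subject`, in canonical order.
#' @export
parse_hits <- function(path, catalog = NULL, evalue_cutoff = 1,
                       unknown_subject = c("flag", "error")) {
  unknown_subject <- match.arg(unknown_subject)
  # readr's parsing warning is promoted to an error below
  tab <- suppressWarnings(
    readr::read_tsv(path, col_names = OUTFMT6_COLS,
                    show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(
                           qseqid = "c", sseqid = "c", pident = "d",
                           length = "i", mismatch = "i", gapopen = "i",
                           qstart = "i", qend = "i", sstart = "i",
                           send = "i", evalue = "c", bitscore = "d"
                         )))
  pr <- readr::problems(tab)
  if (nrow(pr)) {
    stop("unparseable alignment row at line ", pr$row[1], " of ", path,
         ": ", pr$expected[1], " expected")
  }
  tab <- dplyr::rename(tab, read_id = "qseqid", gene_id = "sseqid",
                       evalue_text = "evalue")
  tab$evalue <- as.numeric(tab$evalue_text)
  if (anyNA(tab$evalue)) {
    stop("non-numeric E-value at line ", which(is.na(tab$evalue))[1])
  }
  if (any(tab$evalue < 0)) stop("negative E-value encountered")
  tab <- tab[tab$evalue < evalue_cutoff, ]
  if (!is.null(catalog)) {
    tab$known_subject <- tab$gene_id %in% catalog$genes$gene_id
    if (unknown_subject == "error" && !all(tab$known_subject)) {
      stop("unknown subject gene(s): ",
           paste(utils::head(unique(tab$gene_id[!tab$known_subject]), 5),
                 collapse = ", "))
    }
  } else {
    tab$known_subject <- NA
  }
  sort_hits(tab)
}

#' Sort hits into the canonical per-read order
#'
#' E-value ascending, ties broken by bitscore descending, then
#' lexicographic subject gene id. All protocol logic assumes this order.
#'
#' @param hits Hit tibble.
#' @return Sorted hit tibble.
#' @export
sort_hits <- function(hits) {
  hits |>
    dplyr::arrange(.data$read_id, .data$evalue, dplyr::desc(.data$bitscore),
                   .data$gene_id)
}

#' Write hits back to outfmt-6
#'
#' E-values are written from their preserved decimal text so that
#' parse-write-parse round-trips exactly.
#'
#' @param hits Hit tibble from [parse_hits()] or [oracle_align()].
#' @param path Output path.
#' @return `hits`, invisibly.
#' @export
write_hits <- function(hits, path) {
  out <- tibble(
    qseqid = hits$read_id, sseqid = hits$gene_id, pident = hits$pident,
    length = hits$length, mismatch = hits$mismatch, gapopen = hits$gapopen,
    qstart = hits$qstart, qend = hits$qend, sstart = hits$sstart,
    send = hits$send, evalue = hits$evalue_text, bitscore = hits$bitscore
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(hits)
}

#' Specify a phylogenetic database-exclusion filter
#'
#' Simulates an incomplete reference database by removing alignments to
#' the focal read set's own strain, species or genus, or to genomes
#' within a 16S distance cutoff. Removing alignments (rather than
#' rebuilding the database) preserves all database-size-based metrics
#' such as the E-value.
#'
#' @param mode One of `"none"`, `"strain"`, `"species"`, `"genus"`,
#'   `"distance"`.
#' @param focal_taxon Named list with `strain_id`, `species_id`,
#'   `genus_id` (taxon modes).
#' @param distance_cutoff Non-negative cutoff; hits to genomes at
#'   distance strictly below it are removed (mode `"distance"`).
#' @param distance_table Tibble `genome_id`, `distance` covering all
#'   subject genomes (mode `"distance"`).
#' @return An `exclusion_spec`.
#' @export
exclusion_spec <- function(mode = c("none", "strain", "species", "genus",
                                    "distance"),
                           focal_taxon = NULL, distance_cutoff = NULL,
                           distance_table = NULL) {
  mode <- match.arg(mode)
  if (mode %in% c("strain", "species", "genus") && is.null(focal_taxon)) {
    stop("focal_taxon is required for mode = ", mode)
  }
  if (mode == "distance") {
    if (is.null(distance_cutoff) || distance_cutoff < 0) {
      stop("mode = distance requires a non-negative distance_cutoff")
    }
    if (is.null(distance_table)) stop("mode = distance requires a distance_table")
  }
  structure(list(mode = mode, focal_taxon = focal_taxon,
                 distance_cutoff = distance_cutoff,
                 distance_table = distance_table),
            class = "exclusion_spec")
}

#' Apply a database-exclusion filter to hit lists
#'
#' Removes hits whose subject gene belongs to the excluded clade (or lies
#' within the distance cutoff); surviving hits keep their E-values, all
#' other fields, and their order unchanged.
#'
#' @param hits Hit tibble in canonical order.
#' @param spec An [exclusion_spec()].
#' @param catalog A `ko_catalog` resolving subject genes to taxa.
#' @param unknown_taxon `"error"` (default) or `"drop"` for subjects whose
#'   taxon cannot be resolved under a taxon mode.
#' @return Filtered hit tibble.
#' @export
apply_exclusion <- function(hits, spec, catalog,
                            unknown_taxon = c("error", "drop")) {
  unknown_taxon <- match.arg(unknown_taxon)
  if (spec$mode == "none" || !nrow(hits)) return(hits)
  if (spec$mode == "distance") {
    dt <- spec$distance_table
    gmap <- catalog$genes$genome_id[match(hits$gene_id, catalog$genes$gene_id)]
    d <- dt$distance[match(gmap, dt$genome_id)]
    if (anyNA(d)) {
      stop("distance table does not cover genome(s): ",
           paste(unique(gmap[is.na(d)]), collapse = ", "))
    }
    return(hits[d >= spec$distance_cutoff, ])
  }
  level_col <- paste0(spec$mode, "_id")
  idx <- match(hits$gene_id, catalog$genes$gene_id)
  lev <- catalog$genes[[level_col]][idx]
  if (anyNA(lev)) {
    if (unknown_taxon == "error") {
      stop("unknown taxon for subject gene(s): ",
           paste(utils::head(unique(hits$gene_id[is.na(lev)]), 5),
                 collapse = ", "))
    }
    hits <- hits[!is.na(lev), ]
    lev <- lev[!is.na(lev)]
  }
  hits[lev != spec$focal_taxon[[level_col]], ]
}

#' Truncate each read's hit list to the top N with tie extension
#'
#' Returns the first `n` hits in the canonical order for each read,
#' extended to include any hits whose printed E-value ties with the N-th
#' ("the up-to 20 alignments with the smallest E-values"; equal-E hits
#' are treated jointly).
#'
#' @param hits Hit tibble in canonical order.
#' @param n Maximum number of hits per read before tie extension.
#' @return Truncated hit tibble.
#' @export
truncate_top <- function(hits, n = 20L) {
  stopifnot(n >= 1L)
  if (!nrow(hits)) return(hits)
  hits |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter({
      r <- dplyr::row_number()
      if (dplyr::n() <= n) rep(TRUE, dplyr::n())
      else r <= n | .data$evalue_text == .data$evalue_text[n]
    }) |>
    dplyr::ungroup()
}
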