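#' Convert an E-value to the corresponding P-value
#'
#' The E-value is the expected number of chance matches at a given score;
#' under a Poisson model the probability of at least one such match is
#' `P = 1 - exp(-E)`.
#'
#' @param evalue Non-negative E-value(s).
#' @return P-value(s) in `[0, 1)`.
#' @export
pvalue <- function(evalue) {
  if (any(evalue < 0)) stop("E-values must be non-negative")
  -expm1(-evalue)
}

#' Fractional weights for a set of considered alignments
#'
#' Two readings of the P-value weighting are provided. `complement`
#' (default) sets `w_i` proportional to `1 - P_i = exp(-E_i)`, so better
#' (less likely by chance) hits weigh more. `literal` sets `w_i`
#' proportional to `P_i`; when every P is zero (all E = 0) it falls back
#' to uniform weights. Weights always sum to 1.
#'
#' @param evalue Vector of E-values of the considered hits.
#' @param mode `"complement"` or `"literal"`.
#' @return Numeric weights summing to 1.
#' @export
weight_hits <- function(evalue, mode = c("complement", "literal")) {
  mode <- match.arg(mode)
  if (!length(evalue)) stop("cannot weight an empty hit list")
  if (mode == "complement") {
    w <- exp(-evalue)
  } else {
    w <- pvalue(evalue)
    if (sum(w) == 0) w <- rep(1, length(evalue))
  }
  w / sum(w)
}

#' Annotate reads from their filtered hit lists
#'
#' Applies one of the four protocols to each read's canonical-order hit
#' list:
#' \describe{
#'   \item{top_gene}{consider the smallest-E hit(s), ties included; if
#'     none carries a KO the read has `no_result`.}
#'   \item{top_ko}{consider the smallest-E hit(s) among KO-bearing hits
#'     only, ignoring better-scoring KO-less alignments.}
#'   \item{top20_genes}{consider the top `top_n` hits (tie-extended);
#'     weights are computed over all considered hits but only KO-bearing
#'     hits contribute weight to KO assignments, so KO-less hits dilute
#'     the fractional counts.}
#'   \item{top20_kos}{consider only the KO-bearing hits within the top
#'     `top_n`, weights renormalized over those.}
#' }
#'
#' @param hits Hit tibble in canonical order (from [parse_hits()] /
#'   [apply_exclusion()]).
#' @param catalog A `ko_catalog`.
#' @param protocol One of `"top_gene"`, `"top_ko"`, `"top20_genes"`,
#'   `"top20_kos"`.
#' @param reads Optional read tibble (or character vector of read ids);
#'   reads with no surviving hits are then recorded with status
#'   `no_hit`.
#' @param top_n Hits considered by the top-20 protocols (default 20).
#' @param weighting Weighting mode, see [weight_hits()].
#' @return A `ko_annotation` tibble with one row per considered hit
#'   (`read_id`, `status`, `gene_id`, `evalue`, `pvalue`, `weight`,
#'   `is_ko`) plus one `NA`-gene row per `no_result`/`no_hit` read.
#'   Protocol settings are kept as attributes.
#' @export
annotate_reads <- function(hits, catalog,
                           protocol = c("top_gene", "top_ko",
                                        "top20_genes", "top20_kos"),
                           reads = NULL, top_n = 20L,
                           weighting = c("complement", "literal")) {
  protocol <- match.arg(protocol)
  weighting <- match.arg(weighting)
  stopifnot(top_n >= 1L)
  km <- gene_ko_map(catalog)
  hits <- dplyr::mutate(hits,
                        n_kos = lengths(km[.data$gene_id]),
                        is_ko = .data$n_kos > 0L)
  hits$n_kos[is.na(hits$gene_id) | !hits$gene_id %in% names(km)] <- 0L

  considered <- switch(
    protocol,
    top_gene = hits |>
      dplyr::group_by(.data$read_id) |>
      dplyr::filter(.data$evalue_text == .data$evalue_text[1]) |>
      dplyr::ungroup(),
    top_ko = hits |>
      dplyr::filter(.data$is_ko) |>
      dplyr::group_by(.data$read_id) |>
      dplyr::filter(.data$evalue_text == .data$evalue_text[1]) |>
      dplyr::ungroup(),
    top20_genes = truncate_top(hits, top_n),
    top20_kos = truncate_top(hits, top_n) |>
      dplyr::filter(.data$is_ko)
  )
  if (nrow(considered)) {
    considered <- considered |>
      dplyr::group_by(.data$read_id) |>
      dplyr::mutate(weight = weight_hits(.data$evalue, mode = weighting)) |>
      dplyr::ungroup()
    # gene protocols: a read whose considered set carries no KO gets no_result
    status_tbl <- considered |>
      dplyr::group_by(.data$read_id) |>
      dplyr::summarise(status = if (any(.data$is_ko)) "annotated" else "no_result",
                       .groups = "drop")
    considered <- dplyr::left_join(considered, status_tbl, by = "read_id")
  } else {
    considered <- dplyr::mutate(considered, weight = numeric(0),
                                status = character(0))
  }
  out <- considered |>
    dplyr::transmute(read_id = .data$read_id, status = .data$status,
                     gene_id = .data$gene_id, evalue = .data$evalue,
                     pvalue = pvalue(.data$evalue), weight = .data$weight,
                     is_ko = .data$is_ko, n_kos = .data$n_kos)

  all_ids <- if (is.null(reads)) unique(hits$read_id) else {
    if (is.data.frame(reads)) reads$read_id else reads
  }
  # reads whose hits were all filtered out of the protocol's considered
  # set (e.g. top_ko with no KO-bearing hit) are no_result; reads with no
  # hits at all are no_hit
  had_hits <- unique(hits$read_id)
  missing_ids <- setdiff(all_ids, unique(out$read_id))
  if (length(missing_ids)) {
    out <- dplyr::bind_rows(out, tibble(
      read_id = missing_ids,
      status = ifelse(missing_ids %in% had_hits, "no_result", "no_hit"),
      gene_id = NA_character_, evalue = NA_real_, pvalue = NA_real_,
      weight = NA_real_, is_ko = NA, n_kos = NA_integer_
    ))
  }
  out <- dplyr::arrange(out, .data$read_id, .data$evalue, .data$gene_id)
  attr(out, "protocol") <- protocol
  attr(out, "weighting") <- weighting
  attr(out, "top_n") <- top_n
  class(out) <- c("ko_annotation", class(out))
  out
}

#' Collapse an annotation to per-read fractional KO assignments
#'
#' A considered KO-bearing hit contributes its weight to its gene's KOs,
#' split equally across them when the gene carries several. Under
#' `top20_genes`, KO-less considered hits retain their weight but assign
#' nothing, so a read's KO weights may sum to less than 1; under the
#' other protocols annotated reads' KO weights sum to exactly 1.
#'
#' @param annotation A `ko_annotation` from [annotate_reads()].
#' @param catalog The `ko_catalog` used for annotation.
#' @return Tibble `read_id`, `ko_id`, `weight` (annotated reads only),
#'   one row per read-KO pair.
#' @export
ko_assignments <- function(annotation, catalog) {
  km <- gene_ko_map(catalog)
  ann <- annotation |>
    dplyr::filter(.data$status == "annotated", .data$is_ko)
  if (!nrow(ann)) {
    return(tibble(read_id = character(), ko_id = character(),
                  weight = numeric()))
  }
  ann |>
    dplyr::mutate(ko_id = km[.data$gene_id],
                  weight = .data$weight / .data$n_kos) |>
    tidyr::unnest("ko_id") |>
    dplyr::group_by(.data$read_id, .data$ko_id) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
    dplyr::arrange(.data$read_id, .data$ko_id)
}

#' Write per-read KO assignments to TSV
#'
#' One row per read-KO pair, with `status` rows for unannotated reads.
#' Protocol, weighting mode and N are recorded in a header comment.
#'
#' @param annotation A `ko_annotation`.
#' @param catalog The matching `ko_catalog`.
#' @param path Output path.
#' @return The assignment tibble, invisibly.
#' @export
write_assignments <- function(annotation, catalog, path) {
  asg <- ko_assignments(annotation, catalog)
  statuses <- annotation |>
    dplyr::distinct(.data$read_id, .data$status)
  out <- statuses |>
    dplyr::left_join(asg, by = "read_id") |>
    dplyr::arrange(.data$read_id, .data$ko_id)
  hdr <- sprintf("# protocol=%s weighting=%s top_n=%d",
                 attr(annotation, "protocol"), attr(annotation, "weighting"),
                 attr(annotation, "top_n"))
  writeLines(hdr, path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(out)
}
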