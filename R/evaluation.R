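CLASS_LABELS <- c("correct_gene_correct_ko", "incorrect_gene_correct_ko",
                  "incorrect_gene_incorrect_ko", "incorrect_gene_no_ko",
                  "correct_gene_no_ko", "no_result", "no_hit", "skipped")

# split comma strings into character vectors, "" -> character(0)
split_ids <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ",")
  lapply(out, function(v) v[nzchar(v)])
}

#' Classify each read's annotation against ground truth
#'
#' Every considered hit contributes its fractional weight to one
#' classification label. Gene correctness means the hit's subject is the
#' read's gene of origin; KO correctness means the hit's KO set
#' intersects the source gene's KOs. Reads spanning multiple origin
#' categories are excluded by default (the "correct" annotation is not
#' well defined); with `policy = "coverage_weighted"` they participate
#' with their per-category overlap fractions as weights.
#'
#' @param annotation A `ko_annotation` from [annotate_reads()].
#' @param reads Read tibble with provenance columns (from
#'   [generate_reads()]).
#' @param catalog The `ko_catalog`.
#' @param policy `"exclude"` (default) or `"coverage_weighted"` for
#'   MULTI-origin reads.
#' @return Tibble `read_id`, `origin`, `label`, `weight`, `source_gene`,
#'   `source_kos`; per-read label weights sum to 1 (per origin part under
#'   `coverage_weighted`).
#' @export
classify_reads <- function(annotation, reads, catalog,
                           policy = c("exclude", "coverage_weighted")) {
  policy <- match.arg(policy)
  km <- gene_ko_map(catalog)

  prov <- reads[, c("read_id", "origin", "gene_ids", "source_gene",
                    "source_kos", "frac_ko", "frac_non_ko",
                    "frac_intergenic")]

  if (policy == "exclude") {
    parts <- prov |>
      dplyr::filter(.data$origin != "MULTI") |>
      dplyr::mutate(part_origin = .data$origin, part_weight = 1)
    skipped <- prov |>
      dplyr::filter(.data$origin == "MULTI") |>
      dplyr::transmute(read_id = .data$read_id, origin = .data$origin,
                       label = "skipped", weight = 1,
                       source_gene = .data$source_gene,
                       source_kos = .data$source_kos)
  } else {
    # explode MULTI reads into per-category parts weighted by coverage
    parts <- prov |>
      tidyr::pivot_longer(c("frac_ko", "frac_non_ko", "frac_intergenic"),
                          names_to = "part", values_to = "part_weight") |>
      dplyr::filter(.data$part_weight > 0) |>
      dplyr::mutate(part_origin = dplyr::recode(.data$part,
                                                frac_ko = "KO_GENE",
                                                frac_non_ko = "NON_KO_GENE",
                                                frac_intergenic = "INTERGENIC"))
    skipped <- parts[0, c("read_id", "origin")] |>
      dplyr::mutate(label = character(0), weight = numeric(0),
                    source_gene = character(0), source_kos = character(0))
  }

  status_tbl <- annotation |>
    dplyr::distinct(.data$read_id, .data$status)
  parts <- dplyr::left_join(parts, status_tbl, by = "read_id")
  parts$status[is.na(parts$status)] <- "no_hit"

  # classification is per considered alignment: reads whose considered
  # set exists are judged hit by hit even when the protocol reports
  # no_result (a KO-less considered set); only reads without considered
  # alignments keep a bare status label
  considered_ids <- unique(annotation$read_id[!is.na(annotation$gene_id)])
  parts$has_considered <- parts$read_id %in% considered_ids

  unannotated <- parts |>
    dplyr::filter(!.data$has_considered) |>
    dplyr::transmute(read_id = .data$read_id, origin = .data$origin,
                     part_origin = .data$part_origin,
                     label = .data$status, weight = .data$part_weight,
                     source_gene = .data$source_gene,
                     source_kos = .data$source_kos)

  ann_parts <- dplyr::filter(parts, .data$has_considered)
  hit_rows <- annotation |>
    dplyr::filter(!is.na(.data$gene_id)) |>
    dplyr::select("read_id", "gene_id", "weight", "is_ko") |>
    dplyr::inner_join(ann_parts, by = "read_id",
                      relationship = "many-to-many")

  classified <- if (nrow(hit_rows)) {
    # for a MULTI read's gene part, "its gene" is the overlapped gene set;
    # for single-category reads it is the containing gene(s)
    ref_genes <- ifelse(hit_rows$part_origin == "INTERGENIC", "",
                        ifelse(is.na(hit_rows$source_gene),
                               hit_rows$gene_ids, hit_rows$source_gene))
    ref_gene_list <- split_ids(ref_genes)
    gene_correct <- mapply(function(g, ref) g %in% ref,
                           hit_rows$gene_id, ref_gene_list,
                           USE.NAMES = FALSE)
    hit_kos <- km[hit_rows$gene_id]
    ref_kos <- split_ids(ifelse(hit_rows$part_origin == "KO_GENE",
                                hit_rows$source_kos, ""))
    # MULTI KO-part reads: source_kos may be empty if the gene does not
    # fully contain the read; fall back to KOs of overlapped genes
    need_fb <- hit_rows$part_origin == "KO_GENE" &
      !vapply(ref_kos, length, integer(1))
    if (any(need_fb)) {
      ov_gene_list <- split_ids(hit_rows$gene_ids[need_fb])
      ref_kos[need_fb] <- lapply(ov_gene_list, function(g) {
        unique(unlist(km[g]))
      })
      # gene part reference genes likewise fall back to overlapped genes
      gene_correct[need_fb] <- mapply(function(g, ref) g %in% ref,
                                      hit_rows$gene_id[need_fb],
                                      ov_gene_list, USE.NAMES = FALSE)
    }
    ko_correct <- mapply(function(h, ref) length(intersect(h, ref)) > 0,
                         hit_kos, ref_kos, USE.NAMES = FALSE)
    label <- dplyr::case_when(
      hit_rows$part_origin == "KO_GENE" & gene_correct & ko_correct ~
        "correct_gene_correct_ko",
      hit_rows$part_origin == "KO_GENE" & !hit_rows$is_ko ~ "incorrect_gene_no_ko",
      hit_rows$part_origin == "KO_GENE" & ko_correct ~ "incorrect_gene_correct_ko",
      hit_rows$part_origin == "KO_GENE" ~ "incorrect_gene_incorrect_ko",
      hit_rows$part_origin == "NON_KO_GENE" & gene_correct ~ "correct_gene_no_ko",
      hit_rows$part_origin == "NON_KO_GENE" & hit_rows$is_ko ~ "incorrect_gene_incorrect_ko",
      hit_rows$part_origin == "NON_KO_GENE" ~ "incorrect_gene_no_ko",
      hit_rows$is_ko ~ "incorrect_gene_incorrect_ko",
      TRUE ~ "incorrect_gene_no_ko"
    )
    tibble(read_id = hit_rows$read_id, origin = hit_rows$origin,
           part_origin = hit_rows$part_origin, label = label,
           weight = hit_rows$weight * hit_rows$part_weight,
           is_ko_hit = hit_rows$is_ko,
           source_gene = hit_rows$source_gene,
           source_kos = hit_rows$source_kos) |>
      dplyr::group_by(.data$read_id, .data$origin, .data$part_origin,
                      .data$label, .data$is_ko_hit, .data$source_gene,
                      .data$source_kos) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
  } else {
    tibble(read_id = character(), origin = character(),
           part_origin = character(), label = character(),
           weight = numeric(), is_ko_hit = logical(),
           source_gene = character(), source_kos = character())
  }

  skipped$part_origin <- rep("MULTI", nrow(skipped))
  skipped$is_ko_hit <- NA
  unannotated$is_ko_hit <- NA

  out <- dplyr::bind_rows(classified, unannotated, skipped) |>
    dplyr::arrange(.data$read_id, .data$label)
  attr(out, "policy") <- policy
  attr(out, "protocol") <- attr(annotation, "protocol")
  out
}

#' Evaluate an annotation run: weighted precision and recall
#'
#' Reads are the unit and fractional hit weights propagate. KO recall is
#' the summed correct-KO weight over reads originating from KO genes
#' divided by the number of such reads (`no_result`/`no_hit` reads count
#' in the denominator but never against precision). KO precision is the
#' summed correct-KO weight divided by the total weight assigned to any
#' KO across all reads. Gene recall is the correct-gene analogue over all
#' gene-origin reads.
#'
#' @param classifications Output of [classify_reads()].
#' @param dataset_id,protocol,exclusion Optional labels carried into the
#'   summary row.
#' @return An `annotation_eval` object; see [glance.annotation_eval()]
#'   and [tidy.annotation_eval()].
#' @export
evaluate_annotation <- function(classifications, dataset_id = NA_character_,
                                protocol = NULL, exclusion = NA_character_) {
  if (!nrow(classifications)) stop("no classifications to evaluate")
  cl <- classifications
  protocol <- protocol %||% attr(classifications, "protocol") %||% NA_character_
  policy <- attr(classifications, "policy") %||% "exclude"

  correct_ko_labels <- c("correct_gene_correct_ko", "incorrect_gene_correct_ko")
  assigned_ko_labels <- c(correct_ko_labels, "incorrect_gene_incorrect_ko")
  correct_gene_labels <- c("correct_gene_correct_ko", "correct_gene_no_ko")

  ko_parts <- dplyr::filter(cl, .data$part_origin == "KO_GENE")
  gene_parts <- dplyr::filter(cl, .data$part_origin %in%
                                c("KO_GENE", "NON_KO_GENE"))
  # denominator: (fractional) number of KO-gene-origin reads
  n_ko_reads <- ko_parts |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(w = sum(.data$weight), .groups = "drop") |>
    dplyr::pull(.data$w) |>
    sum()
  n_gene_reads <- gene_parts |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(w = sum(.data$weight), .groups = "drop") |>
    dplyr::pull(.data$w) |>
    sum()

  correct_ko_w <- sum(ko_parts$weight[ko_parts$label %in% correct_ko_labels])
  assigned_ko_w <- sum(cl$weight[cl$label %in% assigned_ko_labels &
                                   cl$is_ko_hit %in% TRUE])
  correct_gene_w <- sum(gene_parts$weight[gene_parts$label %in%
                                            correct_gene_labels])

  summary <- tibble(
    dataset_id = dataset_id, protocol = protocol, exclusion = exclusion,
    policy = policy,
    recall_ko = if (n_ko_reads > 0) correct_ko_w / n_ko_reads else NaN,
    precision_ko = if (assigned_ko_w > 0) correct_ko_w / assigned_ko_w else NaN,
    recall_gene = if (n_gene_reads > 0) correct_gene_w / n_gene_reads else NaN,
    n_ko_reads = n_ko_reads, n_gene_reads = n_gene_reads,
    assigned_ko_weight = assigned_ko_w,
    n_reads = dplyr::n_distinct(cl$read_id),
    n_skipped = dplyr::n_distinct(cl$read_id[cl$label == "skipped"])
  )
  by_origin <- cl |>
    dplyr::filter(.data$label != "skipped") |>
    dplyr::group_by(origin = .data$part_origin, .data$label) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")

  structure(list(summary = summary, by_origin = by_origin,
                 classifications = cl),
            class = "annotation_eval")
}

#' @export
print.annotation_eval <- function(x, ...) {
  s <- x$summary
  cat("<annotation_eval> ", s$n_reads, " reads",
      if (!is.na(s$protocol)) paste0(", protocol ", s$protocol), "\n",
      sprintf("  recall_ko = %.4f  precision_ko = %.4f  recall_gene = %.4f\n",
              s$recall_ko, s$precision_ko, s$recall_gene), sep = "")
  invisible(x)
}

#' Glance at an evaluation: one-row metric summary
#'
#' @param x An `annotation_eval`.
#' @param ... Unused.
#' @return One-row tibble with recall/precision metrics and counts.
#' @export
glance.annotation_eval <- function(x, ...) x$summary

#' Tidy an evaluation: per-origin classification weight totals
#'
#' @param x An `annotation_eval`.
#' @param ... Unused.
#' @return Tibble `origin`, `label`, `weight`.
#' @export
tidy.annotation_eval <- function(x, ...) x$by_origin

#' Mappability of reads partially overlapping a KO gene
#'
#' Groups MULTI-origin reads by the number of bases they overlap a KO
#' gene and reports, per group, the mean probability of mapping to the
#' correct KO, to an incorrect KO, to a KO-less gene, or of returning no
#' result. Requires classifications produced with
#' `policy = "coverage_weighted"` so MULTI reads are retained.
#'
#' @param classifications Output of
#'   `classify_reads(..., policy = "coverage_weighted")`.
#' @param reads The read tibble the classifications were computed from.
#' @return Tibble `overlap_bp`, `n_reads`, `p_correct_ko`,
#'   `p_incorrect_ko`, `p_no_ko_gene`, `p_no_result`; probability columns
#'   sum to 1 per row.
#' @export
overlap_mappability <- function(classifications, reads) {
  if (identical(attr(classifications, "policy"), "exclude")) {
    stop("overlap_mappability requires policy = 'coverage_weighted'")
  }
  multi <- reads |>
    dplyr::filter(.data$origin == "MULTI", .data$frac_ko > 0) |>
    dplyr::mutate(overlap_bp = as.integer(round(.data$frac_ko * .data$length)))
  if (!nrow(multi)) {
    return(tibble(overlap_bp = integer(), n_reads = integer(),
                  p_correct_ko = numeric(), p_incorrect_ko = numeric(),
                  p_no_ko_gene = numeric(), p_no_result = numeric()))
  }
  cl <- classifications |>
    dplyr::inner_join(multi[, c("read_id", "overlap_bp")], by = "read_id")
  # judge each read's hits against the KO gene it overlaps: use the
  # KO-part rows, renormalized to per-read probabilities
  per_read <- cl |>
    dplyr::filter(.data$part_origin == "KO_GENE" |
                    .data$label %in% c("no_result", "no_hit")) |>
    dplyr::distinct(.data$read_id, .data$overlap_bp, .data$label,
                    .data$weight) |>
    dplyr::group_by(.data$read_id, .data$overlap_bp) |>
    dplyr::mutate(p = .data$weight / sum(.data$weight)) |>
    dplyr::summarise(
      p_correct_ko = sum(.data$p[.data$label %in%
                                   c("correct_gene_correct_ko",
                                     "incorrect_gene_correct_ko")]),
      p_incorrect_ko = sum(.data$p[.data$label == "incorrect_gene_incorrect_ko"]),
      p_no_ko_gene = sum(.data$p[.data$label %in%
                                   c("incorrect_gene_no_ko",
                                     "correct_gene_no_ko")]),
      p_no_result = sum(.data$p[.data$label %in% c("no_result", "no_hit")]),
      .groups = "drop")
  per_read |>
    dplyr::group_by(.data$overlap_bp) |>
    dplyr::summarise(n_reads = dplyr::n(),
                     p_correct_ko = mean(.data$p_correct_ko),
                     p_incorrect_ko = mean(.data$p_incorrect_ko),
                     p_no_ko_gene = mean(.data$p_no_ko_gene),
                     p_no_result = mean(.data$p_no_result),
                     .groups = "drop") |>
    dplyr::arrange(.data$overlap_bp)
}

#' Write an evaluation summary to TSV
#'
#' @param evals One `annotation_eval` or a list of them.
#' @param path Output path.
#' @return The combined summary tibble, invisibly.
#' @export
write_evaluation <- function(evals, path) {
  if (inherits(evals, "annotation_eval")) evals <- list(evals)
  out <- purrr::map_dfr(evals, glance)
  readr::write_tsv(out, path)
  invisible(out)
}
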