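#' Aggregate per-read assignments into a functional profile
#'
#' The total count for each KO is the sum of all fractional counts toward
#' that KO across reads. Counts are normalized by gene length to correct
#' for length bias in read counts: with `mode = "aligned_gene"` each
#' considered hit's contribution is divided by the length of the gene the
#' read aligned to (a weight-average of reciprocal lengths across hits);
#' with `mode = "ko_mean"` KO totals are divided by the mean length of
#' the KO's member genes.
#'
#' @param annotation A `ko_annotation` from [annotate_reads()].
#' @param catalog The `ko_catalog`.
#' @param mode `"aligned_gene"` (default) or `"ko_mean"`.
#' @return A `functional_profile` tibble: `ko_id`, `count`, `norm_count`,
#'   with the normalization mode as attribute.
#' @export
aggregate_profile <- function(annotation, catalog,
                              mode = c("aligned_gene", "ko_mean")) {
  mode <- match.arg(mode)
  km <- gene_ko_map(catalog)
  len <- stats::setNames(catalog$genes$length, catalog$genes$gene_id)
  ann <- annotation |>
    dplyr::filter(.data$status == "annotated", .data$is_ko)
  if (!nrow(ann)) {
    out <- tibble(ko_id = character(), count = numeric(),
                  norm_count = numeric())
    attr(out, "mode") <- mode
    class(out) <- c("functional_profile", class(out))
    return(out)
  }
  glen <- unname(len[ann$gene_id])
  if (any(is.na(glen) | glen <= 0)) {
    stop("missing or non-positive length for subject gene(s): ",
         paste(utils::head(unique(ann$gene_id[is.na(glen) | glen <= 0]), 5),
               collapse = ", "))
  }
  long <- ann |>
    dplyr::mutate(gene_length = glen,
                  ko_id = km[.data$gene_id],
                  w = .data$weight / .data$n_kos) |>
    tidyr::unnest("ko_id")
  prof <- long |>
    dplyr::group_by(.data$ko_id, .data$gene_id, .data$gene_length) |>
    dplyr::summarise(count = sum(.data$w), .groups = "drop") |>
    dplyr::group_by(.data$ko_id) |>
    dplyr::summarise(norm_count = sum(.data$count / .data$gene_length),
                     count = sum(.data$count),
                     .groups = "drop") |>
    dplyr::select("ko_id", "count", "norm_count")
  if (mode == "ko_mean") {
    mean_len <- catalog$ko_genes |>
      dplyr::mutate(length = len[.data$gene_id]) |>
      dplyr::group_by(.data$ko_id) |>
      dplyr::summarise(mean_length = mean(.data$length), .groups = "drop")
    prof <- prof |>
      dplyr::left_join(mean_len, by = "ko_id") |>
      dplyr::mutate(norm_count = .data$count / .data$mean_length) |>
      dplyr::select(-"mean_length")
  }
  prof <- dplyr::arrange(prof, .data$ko_id)
  attr(prof, "mode") <- mode
  class(prof) <- c("functional_profile", class(prof))
  prof
}

#' Estimate KO copy numbers from a profile
#'
#' Divides each KO's length-normalized count by the mean normalized count
#' of a set of universal single-copy marker KOs (the 15 ribosomal
#' single-copy genes in real catalogs; synthetic communities declare
#' their own markers). Markers absent from the profile enter the mean as
#' zero.
#'
#' @param profile A `functional_profile`.
#' @param markers Character vector of marker KO ids.
#' @param kos Optional KO universe; absent KOs are reported with copy
#'   number 0.
#' @return `profile` with a `copy_number` column.
#' @export
estimate_copy_numbers <- function(profile, markers, kos = NULL) {
  stopifnot(length(markers) >= 1L)
  norm <- stats::setNames(profile$norm_count, profile$ko_id)
  marker_norm <- norm[markers]
  marker_norm[is.na(marker_norm)] <- 0
  denom <- mean(marker_norm)
  if (denom <= 0) stop("no marker KO observed with positive normalized count")
  out <- profile
  if (!is.null(kos)) {
    extra <- setdiff(kos, out$ko_id)
    if (length(extra)) {
      out <- dplyr::bind_rows(out, tibble(ko_id = extra, count = 0,
                                          norm_count = 0))
    }
  }
  out$copy_number <- out$norm_count / denom
  out <- dplyr::arrange(out, .data$ko_id)
  attr(out, "mode") <- attr(profile, "mode")
  attr(out, "markers") <- markers
  class(out) <- unique(c("functional_profile", class(out)))
  out
}

# Shannon entropy (base 2) of a probability vector; 0 log 0 = 0.
entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Jensen-Shannon distance between two profiles
#'
#' Square root of the Jensen-Shannon divergence with base-2 logarithms,
#' a bounded metric on probability distributions. Inputs are zero-filled
#' over the union of their names and normalized to sum 1, so raw copy
#' numbers or abundances can be passed directly.
#'
#' @param p,q Named non-negative numeric vectors (e.g. `copy_number` or
#'   `norm_count` columns named by `ko_id`), or `functional_profile`
#'   objects.
#' @param values Column used when profiles are passed
#'   (default `"copy_number"` if present, else `"norm_count"`).
#' @return Distance in `[0, 1]`.
#' @export
jsd_distance <- function(p, q, values = NULL) {
  as_vec <- function(x) {
    if (inherits(x, "functional_profile") || is.data.frame(x)) {
      col <- values %||%
        (if ("copy_number" %in% names(x)) "copy_number" else "norm_count")
      stats::setNames(x[[col]], x$ko_id)
    } else x
  }
  p <- as_vec(p); q <- as_vec(q)
  keys <- union(names(p), names(q))
  if (is.null(keys) && length(p) == length(q)) keys <- seq_along(p)
  pv <- rep(0, length(keys)); qv <- rep(0, length(keys))
  if (is.null(names(p))) pv <- as.numeric(p) else pv[match(names(p), keys)] <- p
  if (is.null(names(q))) qv <- as.numeric(q) else qv[match(names(q), keys)] <- q
  if (any(pv < 0) || any(qv < 0)) stop("profiles must be non-negative")
  if (sum(pv) == 0 || sum(qv) == 0) stop("cannot normalize an all-zero profile")
  pv <- pv / sum(pv); qv <- qv / sum(qv)
  m <- (pv + qv) / 2
  jsd <- entropy2(m) - (entropy2(pv) + entropy2(qv)) / 2
  sqrt(min(max(jsd, 0), 1))
}

#' Per-KO recall with gene-property covariates
#'
#' Computes, for every KO observed as a read origin, the recall for
#' identifying reads originating from that KO, per dataset and averaged
#' across datasets with a normal-approximation 95% CI. The catalog
#' contributes each KO's gene-property vector (length mean/SD/CV, gene
#' and genome counts, genes-per-genome mean/SD) used to probe
#' determinants of mappability.
#'
#' @param classifications A single classification tibble or a (possibly
#'   named) list of them, one per dataset.
#' @param catalog The `ko_catalog`.
#' @return Tibble with one row per KO: `ko_id`, `mean_recall`,
#'   `ci_lower`, `ci_upper`, `n_datasets`, and the property columns.
#' @export
per_ko_recall <- function(classifications, catalog) {
  if (is.data.frame(classifications)) classifications <- list(classifications)
  if (!length(classifications)) stop("at least one dataset is required")
  correct <- c("correct_gene_correct_ko", "incorrect_gene_correct_ko")
  per_ds <- purrr::imap_dfr(classifications, function(cl, ds) {
    cl |>
      dplyr::filter(.data$part_origin == "KO_GENE",
                    !is.na(.data$source_kos), nzchar(.data$source_kos)) |>
      dplyr::mutate(ko_id = split_ids(.data$source_kos)) |>
      tidyr::unnest("ko_id") |>
      dplyr::group_by(.data$ko_id) |>
      dplyr::summarise(
        recall = sum(.data$weight[.data$label %in% correct]) /
          sum(.data$weight),
        .groups = "drop") |>
      dplyr::mutate(dataset = as.character(ds))
  })
  stats_tbl <- per_ds |>
    dplyr::group_by(.data$ko_id) |>
    dplyr::summarise(
      mean_recall = mean(.data$recall),
      sd_recall = stats::sd(.data$recall),
      n_datasets = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(
      se = ifelse(.data$n_datasets > 1,
                  .data$sd_recall / sqrt(.data$n_datasets), 0),
      ci_lower = pmax(0, .data$mean_recall - 1.96 * .data$se),
      ci_upper = pmin(1, .data$mean_recall + 1.96 * .data$se)) |>
    dplyr::select(-"se", -"sd_recall")

  len <- stats::setNames(catalog$genes$length, catalog$genes$gene_id)
  genome <- stats::setNames(catalog$genes$genome_id, catalog$genes$gene_id)
  props <- catalog$ko_genes |>
    dplyr::mutate(length = len[.data$gene_id],
                  genome_id = genome[.data$gene_id]) |>
    dplyr::group_by(.data$ko_id) |>
    dplyr::summarise(
      mean_gene_length = mean(.data$length),
      sd_gene_length = ifelse(dplyr::n() > 1, stats::sd(.data$length), 0),
      n_genes = dplyr::n(),
      n_genomes = dplyr::n_distinct(.data$genome_id),
      genes_per_genome_mean = dplyr::n() / dplyr::n_distinct(.data$genome_id),
      genes_per_genome_sd = stats::sd(table(factor(.data$genome_id))),
      .groups = "drop") |>
    dplyr::mutate(
      cv_gene_length = .data$sd_gene_length / .data$mean_gene_length,
      genes_per_genome_sd = ifelse(is.na(.data$genes_per_genome_sd), 0,
                                   .data$genes_per_genome_sd))
  sim <- attr(catalog, "cross_ko_similarity")
  out <- dplyr::left_join(stats_tbl, props, by = "ko_id") |>
    dplyr::mutate(cross_ko_similarity = if (is.null(sim)) NA_real_ else
      unname(sim[.data$ko_id]))
  dplyr::arrange(out, dplyr::desc(.data$mean_recall), .data$ko_id)
}

#' Select the lowest-recall KOs
#'
#' Returns the KOs in the bottom `quantile` of mean recall, with ties at
#' the boundary included.
#'
#' @param ko_stats Output of [per_ko_recall()].
#' @param quantile Fraction selected (default 0.05).
#' @return Character vector of KO ids.
#' @export
low_recall_kos <- function(ko_stats, quantile = 0.05) {
  cutoff <- stats::quantile(ko_stats$mean_recall, quantile, type = 1)
  ko_stats$ko_id[ko_stats$mean_recall <= cutoff]
}

#' Hypergeometric pathway enrichment of a KO set
#'
#' One-sided hypergeometric upper-tail test for over-representation of
#' each pathway in `low_set` relative to `universe`, with
#' Benjamini-Hochberg correction. Pathways with no members in the
#' universe are skipped.
#'
#' @param low_set KO ids of interest (e.g. the bottom 5% of recall);
#'   must be a subset of `universe`.
#' @param universe All KO ids under consideration.
#' @param ko_pathways Tibble `ko_id`, `pathway_id`.
#' @param alpha FDR threshold annotated in the `significant` column.
#' @return Tibble `pathway_id`, `overlap`, `pathway_size`, `p`, `q`,
#'   `significant`.
#' @export
pathway_enrichment <- function(low_set, universe, ko_pathways, alpha = 0.05) {
  if (!all(low_set %in% universe)) stop("low_set must be a subset of universe")
  kp <- ko_pathways |>
    dplyr::filter(.data$ko_id %in% universe)
  if (!nrow(kp)) {
    return(tibble(pathway_id = character(), overlap = integer(),
                  pathway_size = integer(), p = numeric(), q = numeric(),
                  significant = logical()))
  }
  res <- kp |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      pathway_size = dplyr::n_distinct(.data$ko_id),
      overlap = dplyr::n_distinct(intersect(.data$ko_id, low_set)),
      .groups = "drop") |>
    dplyr::mutate(
      p = stats::phyper(.data$overlap - 1L, .data$pathway_size,
                        length(universe) - .data$pathway_size,
                        length(low_set), lower.tail = FALSE),
      q = stats::p.adjust(.data$p, method = "BH"),
      significant = .data$q < alpha) |>
    dplyr::arrange(.data$p, .data$pathway_id)
  res
}

#' Aggregate KO profiles to normalized pathway abundance vectors
#'
#' Each KO's abundance is added to every pathway it belongs to, and each
#' sample's pathway vector is normalized by its total pathway count.
#'
#' @param profiles Long tibble `sample_id`, `ko_id`, `abundance`, or a
#'   named list of `functional_profile`s (then `values` selects the
#'   column).
#' @param ko_pathways Tibble `ko_id`, `pathway_id`.
#' @param values Profile column used when a list is given (default
#'   `"norm_count"`).
#' @return Tibble `sample_id`, `pathway_id`, `abundance` with abundances
#'   summing to 1 per sample (all-zero samples are kept at zero and
#'   flagged with a warning).
#' @export
pathway_profiles <- function(profiles, ko_pathways, values = "norm_count") {
  if (!is.data.frame(profiles)) {
    profiles <- purrr::imap_dfr(profiles, function(p, nm) {
      tibble(sample_id = as.character(nm), ko_id = p$ko_id,
             abundance = p[[values]])
    })
  }
  out <- profiles |>
    dplyr::inner_join(ko_pathways, by = "ko_id",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$sample_id, .data$pathway_id) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(total = sum(.data$abundance),
                  abundance = ifelse(.data$total > 0,
                                     .data$abundance / .data$total, 0)) |>
    dplyr::ungroup() |>
    dplyr::select(-"total")
  empties <- setdiff(unique(profiles$sample_id), unique(out$sample_id))
  zero <- unique(out$sample_id[!out$sample_id %in%
                                 out$sample_id[out$abundance > 0]])
  if (length(empties) || length(zero)) {
    warning("sample(s) with empty pathway profile: ",
            paste(c(empties, zero), collapse = ", "))
  }
  dplyr::arrange(out, .data$sample_id, .data$pathway_id)
}

#' Compare annotation protocols on pathway abundance profiles
#'
#' Computes Jensen-Shannon distances between protocols within each sample
#' and between samples within each protocol, and tests each pathway for
#' differential abundance between a reference protocol and every other
#' protocol with a paired Wilcoxon signed-rank test (BH-corrected),
#' restricted to pathways with nonzero paired differences in at least
#' `min_samples` samples.
#'
#' @param pathway_abundances Tibble `sample_id`, `protocol`,
#'   `pathway_id`, `abundance` (e.g. [pathway_profiles()] run per
#'   protocol).
#' @param reference Reference protocol (default `"top_gene"`).
#' @param min_samples Minimum number of samples with a nonzero paired
#'   difference for a pathway to be tested (default 10).
#' @param alpha FDR threshold for the `significant` column.
#' @return A `protocol_comparison` with tibbles `inter_protocol`
#'   (`sample_id`, `protocol_a`, `protocol_b`, `distance`),
#'   `inter_sample` (`protocol`, `sample_a`, `sample_b`, `distance`) and
#'   `differential` (`protocol`, `pathway_id`, `n_diff`, `p`, `q`,
#'   `significant`, `tested`).
#' @export
compare_protocols <- function(pathway_abundances, reference = "top_gene",
                              min_samples = 10L, alpha = 0.05) {
  pa <- pathway_abundances
  protos <- sort(unique(pa$protocol))
  samples <- sort(unique(pa$sample_id))
  if (length(protos) < 2L) stop("need at least two protocols")
  if (length(samples) < 2L) stop("need at least two samples")
  if (!reference %in% protos) stop("reference protocol not present")
  cover <- pa |>
    dplyr::distinct(.data$sample_id, .data$protocol) |>
    dplyr::count(.data$protocol)
  if (dplyr::n_distinct(cover$n) != 1L) {
    stop("protocols cover mismatched sample sets")
  }
  wide <- pa |>
    tidyr::pivot_wider(names_from = "pathway_id", values_from = "abundance",
                       values_fill = 0)
  vec_of <- function(s, p) {
    row <- wide[wide$sample_id == s & wide$protocol == p, , drop = FALSE]
    unlist(row[, setdiff(names(row), c("sample_id", "protocol"))])
  }
  inter_protocol <- purrr::map_dfr(samples, function(s) {
    cmb <- utils::combn(protos, 2)
    tibble(sample_id = s, protocol_a = cmb[1, ], protocol_b = cmb[2, ],
           distance = purrr::map2_dbl(cmb[1, ], cmb[2, ], function(a, b) {
             jsd_distance(vec_of(s, a), vec_of(s, b))
           }))
  })
  inter_sample <- purrr::map_dfr(protos, function(p) {
    cmb <- utils::combn(samples, 2)
    tibble(protocol = p, sample_a = cmb[1, ], sample_b = cmb[2, ],
           distance = purrr::map2_dbl(cmb[1, ], cmb[2, ], function(a, b) {
             jsd_distance(vec_of(a, p), vec_of(b, p))
           }))
  })
  pathways <- setdiff(names(wide), c("sample_id", "protocol"))
  differential <- purrr::map_dfr(setdiff(protos, reference), function(p) {
    purrr::map_dfr(pathways, function(pw) {
      ref_v <- vapply(samples, function(s) vec_of(s, reference)[[pw]],
                      numeric(1))
      oth_v <- vapply(samples, function(s) vec_of(s, p)[[pw]], numeric(1))
      d <- oth_v - ref_v
      n_diff <- sum(d != 0)
      tested <- n_diff >= min_samples
      pval <- if (tested) {
        suppressWarnings(stats::wilcox.test(oth_v, ref_v, paired = TRUE,
                                            exact = FALSE)$p.value)
      } else NA_real_
      tibble(protocol = p, pathway_id = pw, n_diff = n_diff,
             tested = tested, p = pval)
    }) |>
      dplyr::mutate(q = ifelse(.data$tested,
                               stats::p.adjust(.data$p, method = "BH"),
                               NA_real_),
                    significant = !is.na(.data$q) & .data$q < alpha)
  })
  structure(list(inter_protocol = inter_protocol,
                 inter_sample = inter_sample,
                 differential = differential,
                 reference = reference, min_samples = min_samples),
            class = "protocol_comparison")
}

#' @export
print.protocol_comparison <- function(x, ...) {
  cat("<protocol_comparison> reference =", x$reference, "\n")
  cat(sprintf("  mean inter-protocol JSD: %.4f\n",
              mean(x$inter_protocol$distance)))
  cat(sprintf("  mean inter-sample   JSD: %.4f\n",
              mean(x$inter_sample$distance)))
  cat(sprintf("  differentially abundant pathways: %d of %d tested\n",
              sum(x$differential$significant),
              sum(x$differential$tested)))
  invisible(x)
}

#' Tidy a protocol comparison: per-pathway differential-abundance table
#'
#' @param x A `protocol_comparison`.
#' @param ... Unused.
#' @return The `differential` tibble.
#' @export
tidy.protocol_comparison <- function(x, ...) x$differential

#' Glance at a protocol comparison
#'
#' @param x A `protocol_comparison`.
#' @param ... Unused.
#' @return One-row tibble with mean inter-protocol and inter-sample
#'   distances, their ratio, and differential-abundance counts.
#' @export
glance.protocol_comparison <- function(x, ...) {
  tibble(
    mean_inter_protocol = mean(x$inter_protocol$distance),
    mean_inter_sample = mean(x$inter_sample$distance),
    ratio = mean(x$inter_protocol$distance) /
      mean(x$inter_sample$distance),
    n_tested = sum(x$differential$tested),
    n_significant = sum(x$differential$significant)
  )
}

#' Write a functional profile to TSV
#'
#' @param profile A `functional_profile`.
#' @param path Output path.
#' @return `profile`, invisibly.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(profile)
}
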