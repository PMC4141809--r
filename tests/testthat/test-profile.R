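test_that("profile aggregation divides by aligned-gene length and conserves weight", {
  fx <- worked_fixtures()$F2
  cat <- fx$catalog
  # 400 unit-weight reads aligned to a 300 bp gene
  h <- sort_hits(hit_row(sprintf("x%03d", 1:400), "dup.1", 1e-12))
  ann <- annotate_reads(h, cat, "top_gene")
  prof <- aggregate_profile(ann, cat)
  expect_equal(prof$count[prof$ko_id == "FDUP"], 400)
  expect_equal(prof$norm_count[prof$ko_id == "FDUP"], 400 / 300)

  # a read split between two KOs contributes fractionally
  h2 <- sort_hits(dplyr::bind_rows(hit_row("y1", "m1", 1e-10),
                                   hit_row("y1", "m2", 1e-10)))
  p2 <- aggregate_profile(annotate_reads(h2, cat, "top_gene"), cat)
  expect_equal(p2$count[p2$ko_id == "FM1"], 0.5)
  expect_equal(p2$count[p2$ko_id == "FM2"], 0.5)

  # total weight conservation
  ann_all <- annotate_reads(fx$hits, cat, "top_gene", reads = fx$reads)
  prof_all <- aggregate_profile(ann_all, cat)
  expect_equal(sum(prof_all$count),
               sum(ko_assignments(ann_all, cat)$weight))

  # empty assignment table gives an empty profile
  p0 <- aggregate_profile(annotate_reads(fx$hits[0, ], cat, "top_gene"), cat)
  expect_equal(nrow(p0), 0L)

  # ko_mean normalization divides totals by mean member length
  pk <- aggregate_profile(ann_all, cat, mode = "ko_mean")
  expect_equal(pk$norm_count, pk$count / 300)
})

test_that("copy numbers are marker-relative and exact on the worked fixture", {
  fx <- worked_fixtures()$F2
  ann <- annotate_reads(fx$hits, fx$catalog, "top_gene", reads = fx$reads)
  prof <- aggregate_profile(ann, fx$catalog)
  cn <- estimate_copy_numbers(prof, fx$markers)
  expect_equal(cn$copy_number[cn$ko_id == "FDUP"], 2.0)
  expect_equal(cn$copy_number[cn$ko_id %in% fx$markers], rep(1, 3))
  # a marker's own copy number includes itself in the mean
  expect_equal(cn$copy_number[cn$ko_id == "FM1"],
               prof$norm_count[prof$ko_id == "FM1"] /
                 mean(prof$norm_count[prof$ko_id %in% fx$markers]))
  # absent KOs report zero when a universe is supplied
  cn2 <- estimate_copy_numbers(prof, fx$markers,
                               kos = c(catalog_kos(fx$catalog), "KGHOST"))
  expect_equal(cn2$copy_number[cn2$ko_id == "KGHOST"], 0)
  expect_error(estimate_copy_numbers(prof[prof$ko_id == "FDUP", ],
                                     fx$markers), "marker")
})

test_that("the Jensen-Shannon distance is a bounded metric", {
  p <- c(a = 0.5, b = 0.5)
  expect_equal(jsd_distance(p, p), 0)
  expect_equal(jsd_distance(c(a = 1), c(b = 1)), 1)  # disjoint supports
  q <- c(a = 0.25, b = 0.75)
  expect_equal(jsd_distance(p, q), bf_jsd(c(0.5, 0.5), c(0.25, 0.75)))
  expect_error(jsd_distance(c(a = 0), c(a = 1)), "all-zero")

  withr::with_seed(5, {
    for (i in 1:100) {
      n <- sample(2:6, 1)
      nm <- paste0("k", 1:n)
      x <- stats::setNames(stats::runif(n), nm)
      y <- stats::setNames(stats::runif(n), nm)
      z <- stats::setNames(stats::runif(n), nm)
      dxy <- jsd_distance(x, y); dyx <- jsd_distance(y, x)
      expect_equal(dxy, dyx)                        # symmetry
      expect_equal(dxy, bf_jsd(x, y))               # oracle equality
      expect_gte(dxy, 0); expect_lte(dxy, 1)        # bounds
      expect_equal(jsd_distance(x, x), 0)           # identity
      dxz <- jsd_distance(x, z); dzy <- jsd_distance(z, y)
      expect_lte(dxy, dxz + dzy + 1e-12)            # triangle inequality
    }
  })
})

test_that("per-KO recall averages datasets and carries gene properties", {
  comm <- build_community(community_spec(genes_per_genome = 10L,
                                         n_markers = 2L, seed = 41L))
  reads <- generate_reads(comm$genomes[[1]], 101, 10)
  cat <- comm$catalog
  mk_cls <- function(oseed, corrupt) {
    h <- oracle_align(reads, comm,
                      oracle_spec(homolog_evalues = NULL,
                                  corruption_rate = corrupt, seed = oseed))
    ann <- annotate_reads(h, cat, "top_gene", reads = reads)
    classify_reads(ann, reads, cat)
  }
  # perfect in both datasets: mean 1, zero-width CI
  ks <- per_ko_recall(list(a = mk_cls(1, 0), b = mk_cls(2, 0)), cat)
  expect_equal(ks$mean_recall, rep(1, nrow(ks)))
  expect_equal(ks$ci_lower, ks$ci_upper)
  expect_true(all(c("mean_gene_length", "cv_gene_length", "n_genes",
                    "n_genomes") %in% names(ks)))
  expect_equal(unique(ks$mean_gene_length), 300)
  # recalled 1.0 and 0.0 averages to 0.5
  none <- mk_cls(3, 1)
  ks2 <- per_ko_recall(list(a = mk_cls(1, 0), b = none), cat)
  expect_equal(ks2$mean_recall, rep(0.5, nrow(ks2)))
  expect_s3_class(plot_recall_by_ko(ks2), "ggplot")
})

test_that("bottom-percentile KO selection keeps boundary ties", {
  ks <- tibble::tibble(ko_id = sprintf("K%03d", 1:100),
                       mean_recall = c(rep(0.1, 3), rep(0.2, 2),
                                       seq(0.3, 1, length.out = 95)))
  low <- low_recall_kos(ks, 0.05)
  expect_equal(length(low), 5L)
  # ties at the boundary are included
  ks2 <- tibble::tibble(ko_id = sprintf("K%03d", 1:100),
                        mean_recall = c(rep(0.1, 8), seq(0.3, 1,
                                                         length.out = 92)))
  expect_equal(length(low_recall_kos(ks2, 0.05)), 8L)
})

test_that("hypergeometric enrichment matches exhaustive subset enumeration", {
  # worked example: universe of 10, pathway of 4, all 3 low KOs inside
  universe <- paste0("K", 1:10)
  kp <- tibble::tibble(ko_id = paste0("K", 1:4), pathway_id = "pw")
  res <- pathway_enrichment(paste0("K", 1:3), universe, kp)
  expect_equal(res$p, choose(4, 3) / choose(10, 3))

  # degenerate cases
  res0 <- pathway_enrichment(paste0("K", 9:10), universe, kp)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p, 1)
  res_all <- pathway_enrichment(universe, universe, kp)
  expect_equal(res_all$overlap, res_all$pathway_size)
  expect_equal(res_all$p, 1)
  expect_error(pathway_enrichment("KX", universe, kp), "subset")

  # randomized equivalence with the enumeration oracle
  withr::with_seed(6, {
    for (i in 1:30) {
      n <- sample(6:12, 1)
      uni <- paste0("U", seq_len(n))
      pw <- sample(uni, sample(2:(n - 1), 1))
      low <- sample(uni, sample(1:4, 1))
      got <- pathway_enrichment(low, uni,
                                tibble::tibble(ko_id = pw, pathway_id = "p"))
      expect_equal(got$p, bf_hyper(got$overlap, pw, uni, length(low)),
                   info = paste("instance", i))
    }
  })
})

test_that("pathway profiles spread multi-membership KOs and normalize", {
  kp <- tibble::tibble(ko_id = c("K1", "K1", "K2"),
                       pathway_id = c("pA", "pB", "pA"))
  prof <- tibble::tibble(sample_id = "s1", ko_id = c("K1", "K2"),
                         abundance = c(2, 6))
  pp <- pathway_profiles(prof, kp)
  # K1 contributes to both pathways before normalization: pA=8, pB=2
  expect_equal(pp$abundance[pp$pathway_id == "pA"], 0.8)
  expect_equal(pp$abundance[pp$pathway_id == "pB"], 0.2)
  expect_equal(sum(pp$abundance), 1)
  # single-pathway sample collapses to 1
  pp2 <- pathway_profiles(tibble::tibble(sample_id = "s", ko_id = "K2",
                                         abundance = 3),
                          kp[kp$ko_id == "K2", ])
  expect_equal(pp2$abundance, 1)
})

test_that("protocol comparison distances, filtering and sign test behave", {
  withr::with_seed(8, {
    samples <- paste0("s", 1:12)
    pws <- paste0("p", 1:5)
    base <- purrr::map_dfr(samples, function(s) {
      v <- stats::runif(5, 0.5, 1.5)
      tibble::tibble(sample_id = s, pathway_id = pws, abundance = v / sum(v))
    })
    # protocol B: constant upward shift in pathway p1 across all samples
    shifted <- base |>
      dplyr::mutate(abundance = ifelse(.data$pathway_id == "p1",
                                       abundance + 0.2, abundance)) |>
      dplyr::group_by(.data$sample_id) |>
      dplyr::mutate(abundance = abundance / sum(abundance)) |>
      dplyr::ungroup()
    pa <- dplyr::bind_rows(
      dplyr::mutate(base, protocol = "top_gene"),
      dplyr::mutate(shifted, protocol = "top_ko")
    )
    cmp <- compare_protocols(pa, min_samples = 10L)
    expect_true(all(cmp$inter_protocol$distance > 0))
    expect_true(cmp$differential$significant[
      cmp$differential$pathway_id == "p1"])
    g <- glance(cmp)
    expect_true(g$ratio > 0)
    expect_s3_class(tidy(cmp), "tbl_df")
    expect_s3_class(autoplot(cmp), "ggplot")

    # identical vectors: zero inter-protocol distance, nothing tested
    pa_same <- dplyr::bind_rows(
      dplyr::mutate(base, protocol = "top_gene"),
      dplyr::mutate(base, protocol = "top_ko")
    )
    cmp_same <- compare_protocols(pa_same, min_samples = 10L)
    expect_equal(cmp_same$inter_protocol$distance,
                 rep(0, nrow(cmp_same$inter_protocol)))
    expect_equal(sum(cmp_same$differential$tested), 0L)

    # pathways differing in too few samples are excluded from testing
    few <- base
    few$abundance[few$sample_id %in% samples[1:5] &
                    few$pathway_id == "p2"] <-
      few$abundance[few$sample_id %in% samples[1:5] &
                      few$pathway_id == "p2"] + 0.1
    pa_few <- dplyr::bind_rows(
      dplyr::mutate(base, protocol = "top_gene"),
      dplyr::mutate(few, protocol = "top_ko")
    )
    cmp_few <- compare_protocols(pa_few, min_samples = 10L)
    expect_false(cmp_few$differential$tested[
      cmp_few$differential$pathway_id == "p2"])

    # mismatched sample sets across protocols are an error
    expect_error(compare_protocols(dplyr::bind_rows(
      dplyr::mutate(base, protocol = "top_gene"),
      dplyr::mutate(dplyr::filter(shifted, .data$sample_id != "s1"),
                    protocol = "top_ko"))), "mismatch")
  })
})
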