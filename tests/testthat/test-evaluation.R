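test_that("single-hit classifications carry the methods' labels", {
  fx <- worked_fixtures()$F1
  cat <- fx$catalog

  # KO-gene read hitting its own gene
  ann <- annotate_reads(hit_row("r1", "gKO", 1e-30), cat, "top_gene")
  cl <- classify_reads(ann, fx$reads[fx$reads$read_id == "r1", ], cat)
  expect_equal(cl$label[cl$read_id == "r1"], "correct_gene_correct_ko")
  expect_equal(cl$weight[cl$read_id == "r1"], 1)

  # KO-gene read hitting a different gene with the same KO
  g2 <- genome_record("other", strrep("ACGT", 150),
                      tibble::tibble(gene_id = "twin", start = 101L,
                                     end = 400L, strand = "+",
                                     ko_ids = "K1"),
                      list(strain_id = "o", species_id = "os",
                           genus_id = "og"))
  cat2 <- build_catalog(c(fx$genomes, list(g2)))
  ann2 <- annotate_reads(hit_row("r1", "twin", 1e-20), cat2, "top_gene")
  cl2 <- classify_reads(ann2, fx$reads[fx$reads$read_id == "r1", ], cat2)
  expect_equal(cl2$label, "incorrect_gene_correct_ko")

  # intergenic read with a KO-bearing hit
  ann3 <- annotate_reads(hit_row("r3", "gK2", 0.1), cat, "top_gene")
  cl3 <- classify_reads(ann3, fx$reads[fx$reads$read_id == "r3", ], cat)
  expect_equal(cl3$label, "incorrect_gene_incorrect_ko")

  # non-KO-gene read hitting its own gene
  ann4 <- annotate_reads(hit_row("r2", "gNON", 1e-20), cat, "top_gene")
  cl4 <- classify_reads(ann4, fx$reads[fx$reads$read_id == "r2", ], cat)
  expect_equal(cl4$label, "correct_gene_no_ko")
  expect_equal(unique(ann4$status), "no_result")  # still no KO annotation
})

test_that("the three-read worked fixture reproduces its hand computation", {
  fx <- worked_fixtures()$F1
  ann <- annotate_reads(fx$hits, fx$catalog, "top_gene", reads = fx$reads)
  ev <- evaluate_annotation(classify_reads(ann, fx$reads, fx$catalog))
  expect_equal(ev$summary$recall_ko, 1.0)
  expect_equal(ev$summary$precision_ko, 0.5)

  ann_ko <- annotate_reads(fx$hits, fx$catalog, "top_ko", reads = fx$reads)
  ev_ko <- evaluate_annotation(classify_reads(ann_ko, fx$reads, fx$catalog))
  expect_equal(ev_ko$summary$precision_ko, 1 / 3)
  expect_equal(ev_ko$summary$recall_ko, 1.0)
})

test_that("per-read class weights sum to one and MULTI policy is honored", {
  g <- toy_genome()
  reads <- generate_reads(g, 101, 13)
  cat <- build_catalog(list(g))
  hits <- sort_hits(purrr::map_dfr(
    reads$read_id[!is.na(reads$source_gene)], function(r) {
      hit_row(r, reads$source_gene[reads$read_id == r], 1e-15)
    }))
  ann <- annotate_reads(hits, cat, "top_gene", reads = reads)

  cl <- classify_reads(ann, reads, cat)
  sums <- c(tapply(cl$weight, cl$read_id, sum))
  expect_equal(unname(sums), rep(1, length(sums)))
  expect_true(all(cl$label[cl$origin == "MULTI"] == "skipped"))

  clw <- classify_reads(ann, reads, cat, policy = "coverage_weighted")
  expect_false(any(clw$label == "skipped"))
  sums_w <- c(tapply(clw$weight, clw$read_id, sum))
  expect_equal(unname(sums_w), rep(1, length(sums_w)))
})

test_that("degenerate all-no-hit input yields zero recall and NaN precision", {
  fx <- worked_fixtures()$F1
  ann <- annotate_reads(fx$hits[0, ], fx$catalog, "top_gene",
                        reads = fx$reads)
  ev <- evaluate_annotation(classify_reads(ann, fx$reads, fx$catalog))
  expect_equal(ev$summary$recall_ko, 0)
  expect_true(is.nan(ev$summary$precision_ko))
  expect_equal(ev$summary$assigned_ko_weight, 0)
})

test_that("a perfect-annotation fixture scores exactly one everywhere", {
  comm <- build_community(community_spec(genes_per_genome = 10L,
                                         n_markers = 3L, seed = 31L))
  reads <- generate_reads(comm$genomes[[1]], 101, 7)
  hits <- oracle_align(reads, comm,
                       oracle_spec(homolog_evalues = NULL, seed = 32L))
  ann <- annotate_reads(hits, comm$catalog, "top_gene", reads = reads)
  ev <- evaluate_annotation(classify_reads(ann, reads, comm$catalog))
  expect_equal(ev$summary$recall_ko, 1)
  expect_equal(ev$summary$precision_ko, 1)
  expect_equal(ev$summary$recall_gene, 1)
})

test_that("precision/recall match the brute-force oracle on random instances", {
  protos <- c("top_gene", "top_ko", "top20_genes", "top20_kos")
  for (seed in 1:25) {
    inst <- random_instance(seed)
    if (!nrow(inst$hits)) next
    p <- protos[(seed - 1L) %% 4L + 1L]
    ann <- annotate_reads(inst$hits, inst$catalog, p, reads = inst$reads,
                          top_n = 3L)
    ev <- evaluate_annotation(classify_reads(ann, inst$reads, inst$catalog))
    bf <- bf_metrics(inst$reads, inst$hits, inst$catalog, p, top_n = 3L)
    expect_equal(ev$summary$recall_ko, bf$recall_ko,
                 info = sprintf("seed %d %s", seed, p))
    expect_equal(ev$summary$precision_ko, bf$precision_ko,
                 info = sprintf("seed %d %s", seed, p))
    expect_equal(ev$summary$recall_gene, bf$recall_gene,
                 info = sprintf("seed %d %s", seed, p))
  }
})

test_that("overlap mappability groups boundary reads by gene overlap", {
  g <- toy_genome()  # KO gene 101-400
  L <- 101L
  reads <- generate_reads(g, L, 1L)
  cat <- build_catalog(list(g))
  multi <- reads[reads$origin == "MULTI" & reads$frac_ko > 0, ]
  # grant every partially overlapping read a hit on the KO gene
  hits <- sort_hits(hit_row(multi$read_id, "g1.a", 1e-12))
  ann <- annotate_reads(hits, cat, "top_gene", reads = reads)
  clw <- classify_reads(ann, reads, cat, policy = "coverage_weighted")
  tab <- overlap_mappability(clw, reads)
  expect_true(all(tab$overlap_bp >= 1 & tab$overlap_bp < L))
  expect_equal(tab$p_correct_ko + tab$p_incorrect_ko + tab$p_no_ko_gene +
                 tab$p_no_result, rep(1, nrow(tab)))
  expect_equal(tab$p_correct_ko, rep(1, nrow(tab)))
  # zero-overlap reads never enter the table
  expect_false(any(tab$overlap_bp == 0))
  # and the exclude policy is rejected
  cle <- classify_reads(ann, reads, cat)
  expect_error(overlap_mappability(cle, reads), "coverage_weighted")
})

test_that("tidy/glance expose the evaluation surfaces", {
  fx <- worked_fixtures()$F1
  ann <- annotate_reads(fx$hits, fx$catalog, "top_gene", reads = fx$reads)
  ev <- evaluate_annotation(classify_reads(ann, fx$reads, fx$catalog),
                            dataset_id = "F1", exclusion = "none")
  g <- glance(ev)
  expect_s3_class(g, "tbl_df")
  expect_equal(nrow(g), 1L)
  expect_equal(g$dataset_id, "F1")
  t <- tidy(ev)
  expect_true(all(c("origin", "label", "weight") %in% names(t)))
  expect_s3_class(autoplot(ev), "ggplot")
})
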