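# Two-genome catalog for protocol tests: gKO1a/gKO1b share K1, gKO2 has
# K2, gMulti carries K1+K3, gNone has no KO.
protocol_catalog <- function() {
  g <- toy_genome("pg", n = 4000L, genes = tibble::tibble(
    gene_id = c("gKO1a", "gKO1b", "gKO2", "gMulti", "gNone"),
    start = c(101L, 601L, 1101L, 1601L, 2101L),
    end = c(400L, 900L, 1400L, 1900L, 2400L),
    strand = "+",
    ko_ids = c("K1", "K1", "K2", "K1,K3", "")
  ))
  build_catalog(list(g))
}

test_that("pvalue is the Poisson complement and monotone", {
  expect_equal(pvalue(0), 0)
  expect_equal(pvalue(1e6), 1)
  expect_lt(pvalue(0.1), pvalue(0.2))
  expect_equal(pvalue(0.5), 1 - exp(-0.5))
  expect_error(pvalue(-1), "non-negative")
})

test_that("hit weighting sums to one in both modes", {
  # equal E gives symmetric weights in both modes
  expect_equal(weight_hits(c(1e-5, 1e-5)), c(0.5, 0.5))
  expect_equal(weight_hits(c(1e-5, 1e-5), "literal"), c(0.5, 0.5))
  # near-zero E-values give near-uniform complement weights
  w <- weight_hits(c(1e-30, 1e-25, 1e-4))
  expect_equal(w, rep(1 / 3, 3), tolerance = 1e-3)
  expect_equal(sum(w), 1)
  # literal mode weights by P directly
  wl <- weight_hits(c(0.1, 0.2), "literal")
  p1 <- 1 - exp(-0.1); p2 <- 1 - exp(-0.2)
  expect_equal(wl[1], p1 / (p1 + p2))
  # degenerate all-zero P falls back to uniform
  expect_equal(weight_hits(c(0, 0, 0), "literal"), rep(1 / 3, 3))
  expect_error(weight_hits(numeric(0)), "empty")
})

test_that("the four protocols consider the hits the methods prescribe", {
  cat <- protocol_catalog()
  h <- sort_hits(dplyr::bind_rows(
    hit_row("r1", "gKO1a", 1e-30),
    hit_row("r1", "gKO1b", 1e-25),
    hit_row("r1", "gKO2", 1e-4)
  ))
  # top_gene: single best hit wins outright
  a <- ko_assignments(annotate_reads(h, cat, "top_gene"), cat)
  expect_equal(a$ko_id, "K1")
  expect_equal(a$weight, 1)
  # top20_genes: all three weighted nearly uniformly, two carry K1
  a20 <- ko_assignments(annotate_reads(h, cat, "top20_genes"), cat)
  expect_equal(a20$weight[a20$ko_id == "K1"], 2 / 3, tolerance = 1e-3)
  expect_equal(a20$weight[a20$ko_id == "K2"], 1 / 3, tolerance = 1e-3)

  # non-KO top hit: top_gene gives no_result, top_ko digs deeper
  h2 <- sort_hits(dplyr::bind_rows(
    hit_row("r2", "gNone", 1e-20),
    hit_row("r2", "gKO2", 0.5)
  ))
  ann_gene <- annotate_reads(h2, cat, "top_gene")
  expect_equal(unique(ann_gene$status), "no_result")
  expect_equal(nrow(ko_assignments(ann_gene, cat)), 0L)
  ann_ko <- annotate_reads(h2, cat, "top_ko")
  ak <- ko_assignments(ann_ko, cat)
  expect_equal(ak$ko_id, "K2")
  expect_equal(ak$weight, 1)

  # multi-KO subject splits its weight equally
  h3 <- hit_row("r3", "gMulti", 1e-10)
  am <- ko_assignments(annotate_reads(h3, cat, "top_gene"), cat)
  expect_equal(am$weight[am$ko_id == "K1"], 0.5)
  expect_equal(am$weight[am$ko_id == "K3"], 0.5)
})

test_that("top20_genes lets KO-less hits dilute the fractional counts", {
  cat <- protocol_catalog()
  h <- sort_hits(dplyr::bind_rows(
    hit_row("r1", "gKO1a", 1e-10),
    hit_row("r1", "gNone", 1e-10)
  ))
  d <- ko_assignments(annotate_reads(h, cat, "top20_genes"), cat)
  expect_equal(d$weight, 0.5)           # half the weight went to gNone
  dk <- ko_assignments(annotate_reads(h, cat, "top20_kos"), cat)
  expect_equal(dk$weight, 1)            # renormalized over KO hits only
})

test_that("tied top hits are all used and equal E means equal weight", {
  cat <- protocol_catalog()
  h <- sort_hits(dplyr::bind_rows(
    hit_row("r1", "gKO1a", 1e-20),
    hit_row("r1", "gKO2", 1e-20)
  ))
  a <- ko_assignments(annotate_reads(h, cat, "top_gene"), cat)
  expect_equal(sort(a$ko_id), c("K1", "K2"))
  expect_equal(a$weight, c(0.5, 0.5))
})

test_that("single-hit reads agree across protocols; statuses are distinct", {
  cat <- protocol_catalog()
  h <- hit_row("r1", "gKO2", 1e-8)
  for (p in c("top_gene", "top_ko", "top20_genes", "top20_kos")) {
    a <- ko_assignments(annotate_reads(h, cat, p), cat)
    expect_equal(a$ko_id, "K2", info = p)
    expect_equal(a$weight, 1, info = p)
  }
  # a KO-less single hit: gene protocols say no_result, top_ko too
  hn <- hit_row("r1", "gNone", 1e-8)
  for (p in c("top_gene", "top_ko", "top20_genes", "top20_kos")) {
    ann <- annotate_reads(hn, cat, p)
    expect_equal(unique(ann$status), "no_result", info = p)
  }
  # no hits at all is no_hit, distinct from no_result
  ann0 <- annotate_reads(hn[0, ], cat, "top_gene", reads = c("r1", "r9"))
  expect_setequal(ann0$status, "no_hit")
})

test_that("removing a non-top hit never changes a top_gene assignment", {
  cat <- protocol_catalog()
  withr::with_seed(11, {
    for (i in 1:20) {
      n <- sample(2:6, 1)
      genes <- sample(c("gKO1a", "gKO1b", "gKO2", "gMulti", "gNone"), n,
                      replace = TRUE)
      evs <- sort(10^-sample(2:30, n))
      h <- sort_hits(hit_row("r", genes, evs))
      full <- ko_assignments(annotate_reads(h, cat, "top_gene"), cat)
      drop_idx <- nrow(h)  # worst hit is never in the tied top set here
      pruned <- ko_assignments(
        annotate_reads(h[-drop_idx, ], cat, "top_gene"), cat)
      expect_equal(as.data.frame(pruned), as.data.frame(full))
    }
  })
})

test_that("assignment weights per annotated read respect the protocol sums", {
  cat <- protocol_catalog()
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(1:8, 1)
      genes <- sample(c("gKO1a", "gKO2", "gMulti", "gNone"), n, replace = TRUE)
      h <- sort_hits(hit_row("r", genes, 10^-sample(1:30, n, replace = TRUE)))
      for (p in c("top_gene", "top_ko", "top20_genes", "top20_kos")) {
        ann <- annotate_reads(h, cat, p)
        if (!any(ann$status == "annotated")) next
        s <- sum(ko_assignments(ann, cat)$weight)
        if (p %in% c("top_gene", "top20_genes")) {
          # KO sums equal the KO-bearing share of considered weight:
          # non-KO hits inside the considered set dilute
          expect_equal(s, sum(ann$weight[ann$status == "annotated" &
                                           ann$is_ko]))
          expect_lte(s, 1 + 1e-12)
        } else {
          expect_equal(s, 1)
        }
        # considered-hit weights always sum to 1
        expect_equal(sum(ann$weight[ann$status == "annotated"]), 1)
      }
    }
  })
})

test_that("assignments serialize with a protocol header", {
  cat <- protocol_catalog()
  h <- hit_row("r1", "gKO2", 1e-8)
  ann <- annotate_reads(h, cat, "top20_kos", top_n = 20)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_assignments(ann, cat, path)
  lines <- readLines(path)
  expect_match(lines[1], "protocol=top20_kos")
  expect_match(lines[1], "top_n=20")
})
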