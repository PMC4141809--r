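# Independent brute-force evaluation oracle: plain loops over (read,
# hit, weight, label) tuples, sharing no code with the package's
# vectorized pipeline. Used to cross-check precision/recall.

bf_gene_kos <- function(catalog) {
  out <- lapply(strsplit(catalog$genes$ko_ids, ","), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  names(out) <- catalog$genes$gene_id
  out
}

# considered hits + weights for one read under a protocol (complement
# weighting), via direct enumeration
bf_consider <- function(h, protocol, gk, top_n = 20) {
  if (!nrow(h)) return(NULL)
  h <- h[order(h$evalue, -h$bitscore, h$gene_id), ]
  is_ko <- vapply(h$gene_id, function(g) length(gk[[g]]) > 0, logical(1))
  sel <- switch(protocol,
    top_gene = which(h$evalue_text == h$evalue_text[1]),
    top_ko = {
      kh <- which(is_ko)
      if (!length(kh)) integer(0)
      else kh[h$evalue_text[kh] == h$evalue_text[kh[1]]]
    },
    top20_genes = {
      if (nrow(h) <= top_n) seq_len(nrow(h))
      else which(seq_len(nrow(h)) <= top_n |
                   h$evalue_text == h$evalue_text[top_n])
    },
    top20_kos = {
      top <- if (nrow(h) <= top_n) seq_len(nrow(h))
             else which(seq_len(nrow(h)) <= top_n |
                          h$evalue_text == h$evalue_text[top_n])
      top[is_ko[top]]
    })
  if (!length(sel)) return(NULL)
  w <- exp(-h$evalue[sel])
  list(gene = h$gene_id[sel], weight = w / sum(w), is_ko = is_ko[sel])
}

# full metric computation by enumeration; MULTI reads excluded
bf_metrics <- function(reads, hits, catalog, protocol, top_n = 20) {
  gk <- bf_gene_kos(catalog)
  n_ko_reads <- 0; n_gene_reads <- 0
  correct_ko <- 0; assigned_ko <- 0; correct_gene <- 0
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    if (r$origin == "MULTI") next
    if (r$origin == "KO_GENE") n_ko_reads <- n_ko_reads + 1
    if (r$origin %in% c("KO_GENE", "NON_KO_GENE")) {
      n_gene_reads <- n_gene_reads + 1
    }
    h <- hits[hits$read_id == r$read_id, , drop = FALSE]
    cons <- bf_consider(h, protocol, gk, top_n)
    if (is.null(cons)) next
    src_genes <- strsplit(ifelse(is.na(r$source_gene), "", r$source_gene),
                          ",")[[1]]
    src_kos <- strsplit(ifelse(is.na(r$source_kos), "", r$source_kos),
                        ",")[[1]]
    for (j in seq_along(cons$gene)) {
      g <- cons$gene[j]; w <- cons$weight[j]
      hk <- gk[[g]]
      if (length(hk)) assigned_ko <- assigned_ko + w
      gene_ok <- g %in% src_genes
      ko_ok <- r$origin == "KO_GENE" && length(intersect(hk, src_kos)) > 0
      if (r$origin == "KO_GENE" && ko_ok) correct_ko <- correct_ko + w
      if (r$origin %in% c("KO_GENE", "NON_KO_GENE") && gene_ok) {
        correct_gene <- correct_gene + w
      }
    }
  }
  list(
    recall_ko = if (n_ko_reads > 0) correct_ko / n_ko_reads else NaN,
    precision_ko = if (assigned_ko > 0) correct_ko / assigned_ko else NaN,
    recall_gene = if (n_gene_reads > 0) correct_gene / n_gene_reads else NaN
  )
}

# exhaustive hypergeometric enumeration: P(overlap >= k) over all
# subsets of the universe of the low set's size
bf_hyper <- function(overlap, pathway, universe, low_size) {
  subsets <- utils::combn(universe, low_size)
  hits <- apply(subsets, 2, function(s) sum(s %in% pathway) >= overlap)
  mean(hits)
}

# direct Jensen-Shannon distance from the entropy definition
bf_jsd <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  H <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  m <- (p + q) / 2
  sqrt(H(m) - (H(p) + H(q)) / 2)
}
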