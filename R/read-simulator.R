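#' Generate strided sliding-window reads from a genome
#'
#' Emits every window of length `read_length` starting at positions
#' `1, 1 + step, 1 + 2 step, ...`. A linear genome of length G yields
#' exactly `floor((G - read_length) / step) + 1` reads; a circular genome
#' wraps windows past the origin so every start position on the stride is
#' used. Each read carries its origin category (KO gene / non-KO gene /
#' intergenic / MULTI), the genes it overlaps, and per-category overlap
#' fractions.
#'
#' @param genome A `genome_record`.
#' @param read_length Window size L in bp.
#' @param step Stride in bp (>= 1). The whole-genome scans use 1; a
#'   10-bp stride gives every 10th possible read.
#' @return Tibble with columns `read_id`, `genome_id`, `start`, `length`,
#'   `sequence`, `origin`, `gene_ids`, `source_gene`, `source_kos`,
#'   `frac_ko`, `frac_non_ko`, `frac_intergenic`.
#' @export
generate_reads <- function(genome, read_length, step = 1L) {
  L <- as.integer(read_length)
  step <- as.integer(step)
  stopifnot(L > 0L, step >= 1L)
  G <- nchar(genome$sequence)
  if (genome$topology == "linear") {
    if (L > G) stop("read length ", L, " exceeds linear genome length ", G)
    starts <- seq.int(1L, G - L + 1L, by = step)
  } else {
    starts <- seq.int(1L, G, by = step)
  }
  seqsrc <- if (genome$topology == "circular") {
    paste0(genome$sequence, substr(genome$sequence, 1L, min(L - 1L, G)))
  } else {
    genome$sequence
  }
  cls <- classify_intervals(genome, starts, L)
  tibble(
    read_id = sprintf("%s|%d|%d", genome$genome_id, starts, L),
    genome_id = genome$genome_id,
    start = starts,
    length = L,
    sequence = substring(seqsrc, starts, starts + L - 1L)
  ) |>
    dplyr::bind_cols(cls)
}

#' Read a position-dependent error profile
#'
#' Two-column TSV (`position`, `rate`), optionally followed by a 16-row
#' substitution block (`from`, `to`, `prob`) in a second file. The
#' aggregate `base_rate` is the mean per-position rate, computed rather
#' than declared.
#'
#' @param path Path to the two-column TSV.
#' @param substitution_path Optional path to a three-column TSV giving a
#'   row-stochastic conditional substitution matrix (zero diagonal).
#' @return An `error_profile`: list with `rate` (numeric vector indexed by
#'   read position), `substitution_matrix` (4x4 or NULL), `base_rate`.
#' @export
read_error_profile <- function(path, substitution_path = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, col_types = "id")
  tab <- tab[order(tab$position), ]
  sub <- NULL
  if (!is.null(substitution_path)) {
    st <- readr::read_tsv(substitution_path, show_col_types = FALSE,
                          col_types = "ccd")
    sub <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                           c("A", "C", "G", "T")))
    sub[cbind(st$from, st$to)] <- st$prob
  }
  error_profile(tab$rate, sub)
}

#' Construct an error profile from a per-position rate vector
#'
#' @param rate Numeric vector of per-position substitution probabilities.
#' @param substitution_matrix Optional 4x4 row-stochastic matrix with zero
#'   diagonal (rows/cols A, C, G, T) giving replacement-base probabilities.
#' @return An `error_profile`.
#' @export
error_profile <- function(rate, substitution_matrix = NULL) {
  if (any(rate < 0 | rate > 1)) stop("per-position rates must lie in [0, 1]")
  if (!is.null(substitution_matrix)) {
    m <- substitution_matrix
    if (any(abs(diag(m)) > 1e-12) || any(abs(rowSums(m) - 1) > 1e-9)) {
      stop("substitution matrix rows must sum to 1 with zero diagonal")
    }
  }
  structure(list(rate = as.numeric(rate),
                 substitution_matrix = substitution_matrix,
                 base_rate = mean(rate)),
            class = "error_profile")
}

#' Uniform error profile
#'
#' @param rate Constant per-position rate.
#' @param length Number of positions covered.
#' @return An `error_profile`.
#' @export
uniform_error_profile <- function(rate, length) {
  error_profile(rep(rate, length))
}

#' Rescale an error profile to a target aggregate rate
#'
#' Multiplies every per-position rate by a constant factor so that the
#' mean rate over the first `read_length` positions equals `target_rate`,
#' preserving the relative shape of the profile (the uniform magnification
#' used to turn a 0.15% run profile into 1.5% and 3% variants).
#'
#' @param profile An `error_profile`.
#' @param target_rate Desired aggregate rate in `[0, 1]`.
#' @param read_length Positions over which the mean is taken; defaults to
#'   the full profile.
#' @return A rescaled `error_profile`.
#' @export
scale_profile <- function(profile, target_rate, read_length = NULL) {
  stopifnot(target_rate >= 0, target_rate <= 1)
  L <- read_length %||% length(profile$rate)
  if (L > length(profile$rate)) stop("profile shorter than read length")
  base <- mean(profile$rate[seq_len(L)])
  if (base == 0) {
    if (target_rate == 0) return(profile)
    stop("cannot scale an all-zero profile to a positive rate")
  }
  f <- target_rate / base
  new_rate <- profile$rate * f
  over <- which(new_rate > 1 + 1e-12)
  if (length(over)) {
    stop("scaling factor ", signif(f, 4), " pushes position ", over[1],
         " above probability 1")
  }
  error_profile(pmin(new_rate, 1), profile$substitution_matrix)
}

#' Inject position-dependent substitution errors into reads
#'
#' Substitution-only (no indels): each base is independently flipped with
#' the profile's per-position probability; the replacement base is drawn
#' from the substitution matrix row if present, otherwise uniformly over
#' the three alternatives. Non-ACGT bases are never substituted.
#' Identical `(reads, profile, seed)` give identical output.
#'
#' @param reads Read tibble from [generate_reads()] (equal-length
#'   sequences).
#' @param profile An `error_profile` covering the read length.
#' @param seed Integer seed (required).
#' @return `reads` with mutated `sequence` and a list-column `errors`
#'   (tibbles with `offset` 1-based, `from`, `to`).
#' @export
inject_errors <- function(reads, profile, seed) {
  if (missing(seed)) stop("seed is required for error injection")
  L <- unique(reads$length)
  stopifnot(length(L) == 1L)
  if (length(profile$rate) < L) stop("profile covers fewer positions than read length")
  n <- nrow(reads)
  bases <- c("A", "C", "G", "T")
  seqs <- reads$sequence
  err <- vector("list", n)
  withr::with_seed(seed, {
    for (j in seq_len(L)) {
      p <- profile$rate[j]
      if (p == 0) next
      orig <- substr(seqs, j, j)
      flip <- stats::runif(n) < p & orig %in% bases
      idx <- which(flip)
      if (!length(idx)) next
      if (is.null(profile$substitution_matrix)) {
        repl <- vapply(orig[idx], function(b) {
          sample(setdiff(bases, b), 1L)
        }, character(1), USE.NAMES = FALSE)
      } else {
        repl <- vapply(orig[idx], function(b) {
          sample(bases, 1L, prob = profile$substitution_matrix[b, ])
        }, character(1), USE.NAMES = FALSE)
      }
      substr(seqs[idx], j, j) <- repl
      for (k in seq_along(idx)) {
        err[[idx[k]]] <- rbind(err[[idx[k]]],
                               data.frame(offset = j, from = orig[idx[k]],
                                          to = repl[k]))
      }
    }
  })
  reads$sequence <- seqs
  reads$errors <- lapply(err, function(e) {
    if (is.null(e)) tibble(offset = integer(), from = character(),
                           to = character())
    else as_tibble(e)
  })
  reads
}

#' Write reads as FASTA
#'
#' @param reads Read tibble.
#' @param path Output path.
#' @return `reads`, invisibly.
#' @export
write_reads_fasta <- function(reads, path) {
  writeLines(rbind(paste0(">", reads$read_id), reads$sequence), path)
  invisible(reads)
}

#' Write reads as FASTQ with a constant quality placeholder
#'
#' @param reads Read tibble.
#' @param path Output path.
#' @param quality_char Single quality character applied to every base.
#' @return `reads`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  qual <- strrep(quality_char, reads$length)
  writeLines(rbind(paste0("@", reads$read_id), reads$sequence,
                   "+", qual), path)
  invisible(reads)
}

#' Write the read provenance sidecar table
#'
#' Records, for every read, its genome, coordinates, origin category,
#' overlapped genes and per-category overlap fractions.
#'
#' @param reads Read tibble.
#' @param path Output TSV path.
#' @return `reads`, invisibly.
#' @export
write_read_provenance <- function(reads, path) {
  cols <- c("read_id", "genome_id", "start", "length", "origin", "gene_ids",
            "source_gene", "source_kos", "frac_ko", "frac_non_ko",
            "frac_intergenic")
  readr::write_tsv(reads[, intersect(cols, names(reads))], path)
  invisible(reads)
}
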