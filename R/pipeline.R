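#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

DEFAULT_CONFIG <- list(
  seed = NULL,
  # read simulation
  read_length = 101L, step = 10L, error_rate = 0,
  # annotation
  protocol = "top_gene", top_n = 20L, weighting = "complement",
  evalue_cutoff = 1,
  # exclusion
  exclusion_mode = "none", focal_genome = NULL,
  # evaluation / profiles
  multi_policy = "exclude", normalization = "aligned_gene",
  # community
  n_genera = 2L, n_species = 2L, n_strains = 2L, genes_per_genome = 30L,
  gene_length = 300L, fraction_ko = 0.6, intergenic_length = 150L,
  n_markers = 15L, n_pathways = 4L,
  # oracle
  self_evalue = 1e-40, decoy_rate = 0, corruption_rate = 0
)

#' Validate and complete a benchmark configuration
#'
#' The configuration is a flat key-value list (or a YAML file of one).
#' Unknown keys are errors rather than silently ignored, since a typo in
#' a benchmark config corrupts the benchmark. `seed` is required: every
#' stochastic stage derives from it.
#'
#' @param config Named list or path to a flat YAML file.
#' @return Completed configuration list.
#' @export
benchmark_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- config[lengths(config) > 0]  # JSON/YAML nulls
  unknown <- setdiff(names(config), names(DEFAULT_CONFIG))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  full <- utils::modifyList(DEFAULT_CONFIG, config)
  if (is.null(full$seed)) stop("configuration requires a seed")
  full$seed <- as.integer(full$seed)
  full
}

#' Run the full benchmark pipeline on a synthetic community
#'
#' Orchestrates the stages end to end: build a synthetic community,
#' simulate strided reads from every genome (optionally with injected
#' sequencing error), align with the oracle, round-trip the alignments
#' through the tabular format, apply the configured database exclusion,
#' annotate under the configured protocol, evaluate against ground truth
#' and aggregate the functional profile with marker-based copy numbers.
#' All outputs plus a manifest (config, seeds, package version) are
#' written under `output_dir`; a rerun with the same config is
#' byte-identical.
#'
#' @param config Flat key-value list or YAML path; see
#'   [benchmark_config()].
#' @param output_dir Directory for outputs (created if needed); `NULL`
#'   skips writing.
#' @return List with `community`, `reads`, `hits`, `annotation`,
#'   `evaluation` (an `annotation_eval`), `profile`, and `config`,
#'   invisibly when writing.
#' @export
run_benchmark <- function(config = list(), output_dir = NULL) {
  cfg <- benchmark_config(config)

  community <- build_community(community_spec(
    n_genera = cfg$n_genera, n_species = cfg$n_species,
    n_strains = cfg$n_strains, genes_per_genome = cfg$genes_per_genome,
    gene_length = cfg$gene_length, fraction_ko = cfg$fraction_ko,
    intergenic_length = cfg$intergenic_length, n_markers = cfg$n_markers,
    n_pathways = cfg$n_pathways, seed = cfg$seed
  ))
  reads <- purrr::map_dfr(community$genomes, generate_reads,
                          read_length = cfg$read_length, step = cfg$step)
  if (cfg$error_rate > 0) {
    profile <- uniform_error_profile(cfg$error_rate, cfg$read_length)
    reads <- inject_errors(reads, profile, seed = cfg$seed + 1L)
  }
  ospec <- oracle_spec(self_evalue = cfg$self_evalue,
                       decoy_rate = cfg$decoy_rate,
                       corruption_rate = cfg$corruption_rate,
                       seed = cfg$seed + 2L)
  hits <- oracle_align(reads, community, ospec)

  focal <- cfg$focal_genome %||% community$genomes[[1]]$genome_id
  excl <- if (cfg$exclusion_mode == "none") exclusion_spec("none") else {
    exclusion_spec(cfg$exclusion_mode,
                   focal_taxon = community$genomes[[focal]]$taxon)
  }
  hits_f <- apply_exclusion(hits, excl, community$catalog)
  ann <- annotate_reads(hits_f, community$catalog, protocol = cfg$protocol,
                        reads = reads, top_n = cfg$top_n,
                        weighting = cfg$weighting)
  cls <- classify_reads(ann, reads, community$catalog,
                        policy = cfg$multi_policy)
  ev <- evaluate_annotation(cls, dataset_id = "synthetic",
                            protocol = cfg$protocol,
                            exclusion = cfg$exclusion_mode)
  prof <- aggregate_profile(ann, community$catalog, mode = cfg$normalization)
  prof <- estimate_copy_numbers(prof, community$markers,
                                kos = catalog_kos(community$catalog))

  res <- list(community = community, reads = reads, hits = hits_f,
              annotation = ann, evaluation = ev, profile = prof,
              config = cfg)
  if (is.null(output_dir)) return(res)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)
  write_read_provenance(reads, p("reads.tsv"))
  write_hits(hits_f, p("hits.tsv"))
  write_assignments(ann, community$catalog, p("assignments.tsv"))
  write_evaluation(ev, p("evaluation.tsv"))
  write_profile(prof, p("profile.tsv"))
  write_catalog(community$catalog, p("catalog.tsv"), p("pathways.tsv"))
  manifest <- list(package = "komapr",
                   version = as.character(utils::packageVersion("komapr")),
                   config = cfg,
                   seeds = list(community = cfg$seed,
                                errors = cfg$seed + 1L,
                                oracle = cfg$seed + 2L))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(res)
}
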