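# End-to-end pipeline commands: simulate fixtures, resolve a library,
# metabarcode bulk samples.  Each command is reproducible byte-for-byte from
# (inputs, config, seed); nested stage seeds derive deterministically from
# the global seed.

#' Pipeline configuration
#'
#' Bundles the stage configurations with output paths and a global seed.
#' Stage seeds derive deterministically from the global seed (library
#' generator: `seed`; bulk sampler: `seed + 500`; bootstrap: `seed + 900`),
#' so a single integer reproduces an entire run.
#'
#' @param out_dir output directory for all pipeline files.
#' @param seed global integer seed.
#' @param sim a [sim_config()] (its seed is overridden by `seed`).
#' @param bulk a [bulk_config()] (seed overridden by `seed + 500`).
#' @param resolution a [resolution_config()].
#' @param phylo a [phylo_config()] (seed overridden by `seed + 900`); the
#'   pipeline default reduces bootstrap replicates to 100.
#' @param assignment an [assignment_config()].
#' @param curation a [curation_config()].
#' @param scoring an [align_scoring()].
#' @param verbose emit progress messages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "refbarcode_out", seed = 1L,
                            sim = sim_config(), bulk = bulk_config(),
                            resolution = resolution_config(),
                            phylo = phylo_config(n_bootstrap = 100L),
                            assignment = assignment_config(),
                            curation = curation_config(),
                            scoring = align_scoring(), verbose = TRUE) {
  seed <- as.integer(seed)
  sim$seed <- seed
  bulk$seed <- seed + 500L
  phylo$seed <- seed + 900L
  structure(list(out_dir = out_dir, seed = seed, sim = sim, bulk = bulk,
                 resolution = resolution, phylo = phylo,
                 assignment = assignment, curation = curation,
                 scoring = scoring, verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

.log <- function(config, ...) {
  if (config$verbose) message(sprintf(...))
}

#' Generate synthetic library and bulk-sample fixtures on disk
#'
#' Writes per-marker FASTA + taxonomy TSV for the reference library, the ASV
#' count table + ASV FASTA for the bulk samples, and TSV truth tables.
#' Idempotent given the seed: re-running produces byte-identical files.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory `library`, `bulk` and truth
#'   objects (the same data that was written).
#' @export
cmd_simulate <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(config$out_dir, 2) != 0) {
    stop("cmd_simulate: output directory not writable: ", config$out_dir)
  }
  .log(config, "simulating library (seed %d)", config$sim$seed)
  sim <- simulate_library(config$sim)
  write_library(sim$library, config$out_dir)
  write.table(sim$truth$taxonomy, file.path(config$out_dir, "truth_taxonomy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  .log(config, "simulating bulk samples (seed %d)", config$bulk$seed)
  bulk <- suppressWarnings(simulate_bulk_samples(sim$library, config$bulk))
  write_asv_table(bulk$table, file.path(config$out_dir, "asv_counts.tsv"),
                  file.path(config$out_dir, "asv_seqs.fasta"))
  write.table(bulk$truth$asvs, file.path(config$out_dir, "truth_asvs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  plot_truth <- data.frame(
    plot = rep(names(bulk$truth$plots), lengths(bulk$truth$plots)),
    species = unlist(bulk$truth$plots, use.names = FALSE))
  write.table(plot_truth, file.path(config$out_dir, "truth_plots.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(library = sim$library, truth = sim$truth, bulk = bulk))
}

#' Barcode and phylogenetic resolution of a reference library
#'
#' Computes the full resolution table (each marker and the combined scope,
#' complete and reduced samplings).  When `with_phylo` is TRUE, a
#' neighbor-joining bootstrap tree is built for every marker whose sequences
#' are equal-length (pre-aligned) and the supported-monophyly block is added
#' for those scopes; markers with length variation are skipped with a
#' warning (tree inference from unaligned sequences is outside this
#' package's scope -- externally built trees can be supplied via
#' [read_newick_with_support()] and [species_monophyly()] instead).
#'
#' @param config a [pipeline_config()].
#' @param lib optional [ref_library()]; defaults to reading the files written
#'   by [cmd_simulate()] from `config$out_dir`.
#' @param all_species optional full species universe for NA accounting.
#' @param with_phylo add the phylogenetic-resolution block.
#' @return The list from [resolution_table()]; also writes
#'   `resolution_summary.tsv`/`.json` and per-scope status TSVs.
#' @export
cmd_resolve <- function(config, lib = NULL, all_species = NULL,
                        with_phylo = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(lib)) {
    markers <- vapply(config$sim$markers, function(p) p$marker_id, character(1))
    files <- setNames(file.path(config$out_dir, paste0(markers, ".fasta")), markers)
    lib <- read_library(files, file.path(config$out_dir, "taxonomy.tsv"))
  }
  phylo_blocks <- NULL
  if (with_phylo) {
    phylo_blocks <- list()
    sm <- species_map(lib)
    for (mk in lib$markers) {
      rec <- lib$records[lib$records$marker_id == mk, ]
      if (nrow(rec) < 3) next
      if (length(unique(nchar(rec$sequence))) != 1) {
        warning("cmd_resolve: marker ", mk,
                " has length variation; phylogenetic block skipped")
        next
      }
      .log(config, "bootstrap tree for %s (%d replicates)", mk,
           config$phylo$n_bootstrap)
      tr <- bootstrap_supports(setNames(rec$sequence, rec$specimen_id),
                               cfg = config$phylo)
      mono <- species_monophyly(tr, sm, config$phylo)
      # species absent from this marker contribute to neither SSA nor SMA
      phylo_blocks[[mk]] <- phylo_summary(mono)
    }
    if (!length(phylo_blocks)) phylo_blocks <- NULL
  }
  res <- resolution_table(lib, cfg = config$resolution, scoring = config$scoring,
                          all_species = all_species, phylo_blocks = phylo_blocks)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_resolution_summary(res$summary,
                           file.path(config$out_dir, "resolution_summary.tsv"),
                           file.path(config$out_dir, "resolution_summary.json"))
  for (nm in names(res$statuses)) {
    write.table(res$statuses[[nm]],
                file.path(config$out_dir, paste0("status_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .log(config, "resolution table written (%d scopes)", nrow(res$summary))
  res
}

#' Metabarcoding assignment, curation and abundance reporting
#'
#' Curates the ASV table, assigns curated ASVs against the reference
#' library, and writes assignment, merge-map and abundance reports.  Stage
#' counts (ASVs in, curated, assigned) are logged.
#'
#' @param config a [pipeline_config()].
#' @param tab optional [asv_table()]; defaults to reading the files written
#'   by [cmd_simulate()].
#' @param lib optional [ref_library()]; defaults likewise.
#' @return List with `assignments`, `curated` (table + merge map) and
#'   `report` (from [abundance_report()]).  An empty ASV table yields empty
#'   outputs with a warning.
#' @export
cmd_metabarcode <- function(config, tab = NULL, lib = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(lib)) {
    markers <- vapply(config$sim$markers, function(p) p$marker_id, character(1))
    files <- setNames(file.path(config$out_dir, paste0(markers, ".fasta")), markers)
    lib <- read_library(files, file.path(config$out_dir, "taxonomy.tsv"))
  }
  if (is.null(tab)) {
    tab <- read_asv_table(file.path(config$out_dir, "asv_counts.tsv"),
                          file.path(config$out_dir, "asv_seqs.fasta"))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (nrow(tab$counts) == 0) {
    warning("cmd_metabarcode: empty ASV table; writing empty reports")
    empty <- data.frame()
    write.table(empty, file.path(config$out_dir, "assignments.tsv"))
    return(invisible(list(assignments = NULL, curated = NULL, report = NULL)))
  }
  .log(config, "ASVs in: %d", nrow(tab$counts))
  cur <- curate(tab, config$curation, config$scoring)
  .log(config, "curated ASVs: %d (merged %d)", nrow(cur$table$counts),
       nrow(cur$merge_map))
  asg <- assign_asvs(cur$table, lib, config$assignment, config$scoring)
  .log(config, "assigned: %d | below threshold: %d | ambiguous: %d",
       sum(asg$status == "assigned"), sum(asg$status == "below_threshold"),
       sum(asg$status == "ambiguous"))
  rep <- abundance_report(cur$table, asg, lib)
  write.table(asg, file.path(config$out_dir, "assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cur$merge_map, file.path(config$out_dir, "merge_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_asv_table(cur$table, file.path(config$out_dir, "asv_counts_curated.tsv"),
                  file.path(config$out_dir, "asv_seqs_curated.fasta"))
  write.table(rep$abundance, file.path(config$out_dir, "abundance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(abundance = rep$abundance,
                            sample_summary = rep$sample_summary,
                            tally = rep$tally),
                       file.path(config$out_dir, "abundance.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(list(assignments = asg, curated = cur, report = rep))
}
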