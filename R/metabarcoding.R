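# ASV species assignment against the reference library and co-occurrence
# curation of erroneous variants, plus the per-plot relative-abundance report.

#' ASV table: sequences plus a count matrix
#'
#' @param sequences named character vector of ASV sequences (names = asv ids).
#' @param counts integer matrix, rows = asv ids, columns = sample ids.
#' @return An object of class `asv_table`.
#' @export
asv_table <- function(sequences, counts) {
  stopifnot(is.character(sequences), is.matrix(counts))
  if (nrow(counts) > 0) {
    stopifnot(!is.null(names(sequences)), !is.null(rownames(counts)))
  } else if (is.null(rownames(counts))) {
    rownames(counts) <- character(0)
  }
  if (!setequal(names(sequences), rownames(counts)) ||
      length(sequences) != nrow(counts)) {
    stop("asv_table: sequence names and count rows must match one-to-one")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("asv_table: counts must be nonnegative integers")
  }
  storage.mode(counts) <- "integer"
  sequences <- toupper(sequences[rownames(counts)])
  structure(list(sequences = sequences, counts = counts), class = "asv_table")
}

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("ASV table: %d ASVs x %d samples, %d reads\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Assignment thresholds for ASV identification
#'
#' Defaults reproduce common local-search filter settings: minimum 95\%
#' identity and 70\% query coverage.
#'
#' @param min_identity minimum percent identity for an assignment.
#' @param min_coverage minimum percent query coverage.
#' @param marker marker id of the reference sequences to search.
#' @return An object of class `assignment_config`.
#' @export
assignment_config <- function(min_identity = 95, min_coverage = 70,
                              marker = "ITS2") {
  stopifnot(min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 100)
  structure(list(min_identity = min_identity, min_coverage = min_coverage,
                 marker = as.character(marker)),
            class = "assignment_config")
}

#' Assign ASVs to species by best reference hit
#'
#' Each ASV (as query) is aligned against every record of the marker; the
#' best hit maximises identity, ties broken by higher coverage.  The ASV is
#' assigned to the best hit's species iff both thresholds are met; when the
#' equally best hits (exact ties on identity and coverage) span more than one
#' species the ASV is `ambiguous`.
#'
#' @param tab an [asv_table()].
#' @param lib a [ref_library()].
#' @param cfg an [assignment_config()].
#' @param scoring an [align_scoring()].
#' @return data.frame with `asv_id`, `status` (`assigned`, `below_threshold`,
#'   `ambiguous`), `species` (NA unless assigned), `best_identity`,
#'   `best_coverage`.
#' @export
assign_asvs <- function(tab, lib, cfg = assignment_config(),
                        scoring = align_scoring()) {
  stopifnot(inherits(tab, "asv_table"), inherits(lib, "ref_library"))
  rec <- lib$records[lib$records$marker_id == cfg$marker, , drop = FALSE]
  if (!nrow(rec)) stop("assign_asvs: library has no records of marker ", cfg$marker)
  ids <- rownames(tab$counts)
  out <- data.frame(asv_id = ids, status = NA_character_, species = NA_character_,
                    best_identity = NA_real_, best_coverage = NA_real_)
  for (k in seq_along(ids)) {
    q <- tab$sequences[[ids[k]]]
    m <- query_stats_cpp(q, rec$sequence, scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
    identity <- ifelse(m[, "n_denom"] > 0, 100 * m[, "n_ident"] / m[, "n_denom"], 0)
    coverage <- 100 * m[, "q_res"] / nchar(q)
    # ratios of small integers order exactly in double precision
    best_i <- max(identity)
    cand <- identity == best_i
    best_c <- max(coverage[cand])
    best <- cand & coverage == best_c
    out$best_identity[k] <- best_i
    out$best_coverage[k] <- best_c
    if (best_i < cfg$min_identity || best_c < cfg$min_coverage) {
      out$status[k] <- "below_threshold"
    } else if (length(unique(rec$species[best])) > 1L) {
      out$status[k] <- "ambiguous"
    } else {
      out$status[k] <- "assigned"
      out$species[k] <- rec$species[best][1]
    }
  }
  out
}

#' Curation settings for collapsing erroneous ASVs
#'
#' Defaults follow the standard co-occurrence curation settings: minimum
#' relative co-occurrence 0.95, minimum similarity 84\%, minimum
#' parent/daughter abundance ratio 1 evaluated as the minimum over
#' co-occurring samples.
#'
#' @param min_cooccurrence minimum fraction of the daughter's samples that
#'   also contain the parent (in (0, 1]).
#' @param min_similarity minimum percent identity between daughter and parent.
#' @param min_ratio minimum parent/daughter per-sample count ratio.
#' @param ratio_type `"min"` (default) or `"avg"` over co-occurring samples.
#' @param min_overlap minimum fraction of the daughter sequence the alignment
#'   overlap region must span for the similarity gate (default 0.9).  Without
#'   it, ends-free alignment of unrelated sequences can degenerate to a short
#'   perfect micro-overlap and report a spuriously high identity; global-
#'   alignment matchers used for this style of curation implicitly require
#'   near-full coverage.
#' @return An object of class `curation_config`.
#' @export
curation_config <- function(min_cooccurrence = 0.95, min_similarity = 84,
                            min_ratio = 1, ratio_type = c("min", "avg"),
                            min_overlap = 0.9) {
  stopifnot(min_cooccurrence > 0, min_cooccurrence <= 1,
            min_similarity >= 0, min_similarity <= 100, min_ratio > 0,
            min_overlap >= 0, min_overlap <= 1)
  structure(list(min_cooccurrence = min_cooccurrence,
                 min_similarity = min_similarity,
                 min_ratio = min_ratio,
                 ratio_type = match.arg(ratio_type),
                 min_overlap = min_overlap),
            class = "curation_config")
}

#' Collapse erroneous ASVs by co-occurrence curation
#'
#' ASVs are processed in increasing total-count order (ties by asv id).  A
#' candidate parent for ASV `d` must have a larger total count, identity to
#' `d` of at least `min_similarity`, relative co-occurrence of at least
#' `min_cooccurrence`, and a parent/daughter abundance ratio over co-occurring
#' samples of at least `min_ratio`.  Among eligible parents, the highest
#' identity wins (ties: higher total count, then asv id).  Eligibility is
#' evaluated on the original counts in a single pass; merge chains are then
#' resolved transitively and daughter counts folded into the final survivors,
#' so total reads are conserved per sample.
#'
#' @param tab an [asv_table()].
#' @param cfg a [curation_config()].
#' @param scoring an [align_scoring()] (similarity uses the same semi-global
#'   identity as every other stage).
#' @return List with `table` (curated [asv_table()]) and `merge_map`
#'   (data.frame `asv_id`, `parent_id`: each merged daughter with its final
#'   surviving parent).
#' @export
curate <- function(tab, cfg = curation_config(), scoring = align_scoring()) {
  stopifnot(inherits(tab, "asv_table"), inherits(cfg, "curation_config"))
  counts <- tab$counts
  n <- nrow(counts)
  if (n <= 1L) {
    return(list(table = tab,
                merge_map = data.frame(asv_id = character(0),
                                       parent_id = character(0))))
  }
  ids <- rownames(counts)
  totals <- rowSums(counts)
  ord <- ids[order(totals, ids)]
  parent_of <- setNames(rep(NA_character_, n), ids)
  for (d in ord) {
    cand <- ids[totals > totals[d]]
    if (!length(cand)) next
    d_samples <- counts[d, ] > 0L
    nd <- sum(d_samples)
    best <- NULL
    best_key <- NULL
    for (p in cand) {
      co <- sum(counts[p, d_samples] > 0L) / nd
      if (co < cfg$min_cooccurrence) next
      shared <- d_samples & counts[p, ] > 0L
      ratios <- counts[p, shared] / counts[d, shared]
      rstat <- if (cfg$ratio_type == "min") min(ratios) else mean(ratios)
      if (rstat < cfg$min_ratio) next
      st <- pair_stats(tab$sequences[[d]], tab$sequences[[p]], scoring)
      if (st$n_denom < cfg$min_overlap * nchar(tab$sequences[[d]])) next
      if (st$identity < cfg$min_similarity) next
      key <- list(identity = st$identity, total = totals[[p]], id = p)
      if (is.null(best_key) ||
          key$identity > best_key$identity ||
          (key$identity == best_key$identity && key$total > best_key$total) ||
          (key$identity == best_key$identity && key$total == best_key$total &&
           key$id < best_key$id)) {
        best <- p
        best_key <- key
      }
    }
    if (!is.null(best)) parent_of[d] <- best
  }
  # resolve chains to final survivors
  final <- parent_of
  for (d in ids) {
    p <- final[[d]]
    while (!is.na(p) && !is.na(parent_of[[p]])) p <- parent_of[[p]]
    final[[d]] <- p
  }
  merged <- ids[!is.na(final)]
  keep <- ids[is.na(final)]
  new_counts <- counts[keep, , drop = FALSE]
  for (d in merged) {
    new_counts[final[[d]], ] <- new_counts[final[[d]], ] + counts[d, ]
  }
  list(table = asv_table(tab$sequences[keep], new_counts),
       merge_map = data.frame(asv_id = merged,
                              parent_id = unname(final[merged])))
}

#' Per-sample relative abundance of assigned species and taxon tally
#'
#' @param tab a (curated) [asv_table()].
#' @param assignments data.frame from [assign_asvs()] covering the table's
#'   ASVs.
#' @param lib a [ref_library()] (provides the genus/family/order of assigned
#'   species for the taxon tally).
#' @return List with: `abundance` (long data.frame `sample`, `species`,
#'   `reads`, `rel_abundance`; shares sum to 1 within each sample with
#'   assigned reads), `sample_summary` (`sample`, `total_reads`,
#'   `assigned_reads`, `unassigned_fraction`), `tally` (distinct species,
#'   genera, families, orders among assigned ASVs), and `empty_samples`
#'   (samples with no assigned reads, flagged rather than reported as 0/0).
#' @export
abundance_report <- function(tab, assignments, lib) {
  stopifnot(inherits(tab, "asv_table"), inherits(lib, "ref_library"))
  if (!all(rownames(tab$counts) %in% assignments$asv_id)) {
    stop("abundance_report: assignments do not cover all ASVs")
  }
  asg <- assignments[match(rownames(tab$counts), assignments$asv_id), ]
  assigned <- asg$status == "assigned"
  samples <- colnames(tab$counts)
  ab_rows <- list()
  total_reads <- colSums(tab$counts)
  assigned_reads <- colSums(tab$counts[assigned, , drop = FALSE])
  for (s in samples) {
    if (assigned_reads[[s]] == 0) next
    cnt <- tab$counts[assigned, s]
    sp_reads <- rowsum(cnt, asg$species[assigned])
    sp_reads <- sp_reads[sp_reads[, 1] > 0, , drop = FALSE]
    ab_rows[[s]] <- data.frame(sample = s, species = rownames(sp_reads),
                               reads = as.integer(sp_reads[, 1]),
                               rel_abundance = sp_reads[, 1] / assigned_reads[[s]])
  }
  abundance <- if (length(ab_rows)) do.call(rbind, c(ab_rows, make.row.names = FALSE))
               else data.frame(sample = character(0), species = character(0),
                               reads = integer(0), rel_abundance = numeric(0))
  tax <- species_taxonomy(lib)
  sp_assigned <- unique(asg$species[assigned])
  ti <- tax[tax$species %in% sp_assigned, , drop = FALSE]
  list(
    abundance = abundance,
    sample_summary = data.frame(
      sample = samples,
      total_reads = as.integer(total_reads),
      assigned_reads = as.integer(assigned_reads),
      unassigned_fraction = ifelse(total_reads > 0,
                                   1 - assigned_reads / total_reads, NA_real_)
    ),
    tally = list(n_species = length(unique(ti$species)),
                 n_genera = length(unique(ti$genus)),
                 n_families = length(unique(ti$family)),
                 n_orders = length(unique(ti$order))),
    empty_samples = samples[assigned_reads == 0]
  )
}

#' Write an ASV table (counts TSV + sequence FASTA)
#'
#' @param tab an [asv_table()].
#' @param counts_path TSV path (first column `asv_id`, one column per sample).
#' @param fasta_path FASTA path for the ASV sequences.
#' @return Invisibly, the two paths.
#' @export
write_asv_table <- function(tab, counts_path, fasta_path) {
  df <- data.frame(asv_id = rownames(tab$counts), tab$counts,
                   check.names = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(tab$sequences), fasta_path)
  invisible(c(counts_path, fasta_path))
}

#' Read an ASV table written by [write_asv_table()]
#'
#' @param counts_path TSV path.
#' @param fasta_path FASTA path.
#' @return An [asv_table()].
#' @export
read_asv_table <- function(counts_path, fasta_path) {
  df <- read.delim(counts_path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$asv_id
  ss <- Biostrings::readDNAStringSet(fasta_path)
  asv_table(setNames(as.character(ss), sub("\\s.*$", "", names(ss))), m)
}
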