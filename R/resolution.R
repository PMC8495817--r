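# Best-match correct-assignment rule and resolution summary statistics.
#
# A query specimen is correctly assigned when (singleton species) no
# heterospecific hit reaches exactly 100% identity, or (multi-accession
# species) its best conspecific identity is at least as high as its best
# heterospecific identity ("similar or higher"; a strict tie policy demands
# strictly higher).  Identity comparisons use exact integer arithmetic on
# (identical, denominator) column counts: within this package's count ranges
# the double quotients a/b are themselves exact for ordering and equality.

#' Configuration of the correct-assignment decision rule
#'
#' @param tie_policy `"pass"` (default) treats an exact conspecific/
#'   heterospecific identity tie as correct ("similar or higher");
#'   `"fail"` demands strictly higher conspecific identity.
#' @param aggregation `"all_queries"` (default): a species is correctly
#'   identified only if every one of its query sequences is; `"any_query"`
#'   requires at least one.
#' @param markers marker scopes to analyse (marker ids and/or `"combined"`).
#' @param sampling `"complete"` or `"reduced"` (species with all markers only).
#' @param min_overlap minimum fraction of the query length that a hit's
#'   overlap region must span for the hit to count toward the decision rule
#'   (default 0.5).  Ends-free alignment of very divergent sequences
#'   degenerates to short perfect micro-overlaps that a significance-filtered
#'   search would never report; this gate emulates that reportability
#'   threshold.  Set to 0 to consider every hit literally.
#' @return An object of class `resolution_config`.
#' @export
resolution_config <- function(tie_policy = c("pass", "fail"),
                              aggregation = c("all_queries", "any_query"),
                              markers = "combined",
                              sampling = c("complete", "reduced"),
                              min_overlap = 0.5) {
  markers <- as.character(markers)
  if (!length(markers)) stop("markers must be nonempty")
  stopifnot(min_overlap >= 0, min_overlap <= 1)
  structure(list(tie_policy = match.arg(tie_policy),
                 aggregation = match.arg(aggregation),
                 markers = markers,
                 sampling = match.arg(sampling),
                 min_overlap = min_overlap),
            class = "resolution_config")
}

#' Is a single query sequence correctly assigned?
#'
#' @param query specimen id of the query.
#' @param hits hit table for the marker scope (complete matrix over the
#'   scope's specimens, e.g. from [all_pairs_identity()] or [combine_hits()]).
#' @param species_of named character vector mapping every specimen in scope to
#'   its species.
#' @param cfg a [resolution_config()].
#' @return Logical scalar.
#' @details A multi-accession query absent from the hit table is a fatal
#'   error (the matrix is incomplete); a singleton query with no hits at all
#'   is correct by the singleton rule (no heterospecific 100% match exists).
#' @export
query_correct <- function(query, hits, species_of, cfg = resolution_config()) {
  sp <- species_of[[query]]
  if (is.null(sp) || is.na(sp)) stop("query_correct: no species for query ", query)
  sel <- hits$query_id == query | hits$subject_id == query
  h <- hits[sel, , drop = FALSE]
  n_raw <- nrow(h)
  if (nrow(h) && cfg$min_overlap > 0) {
    # length of this query in the stored orientation of each hit row
    qlen <- ifelse(h$query_id == query, h$query_length, h$subject_length)
    h <- h[h$n_denom >= cfg$min_overlap * qlen, , drop = FALSE]
  }
  other <- ifelse(h$query_id == query, h$subject_id, h$query_id)
  other_sp <- unname(species_of[other])
  con <- !is.na(other_sp) & other_sp == sp
  if (!any(con)) {
    # singleton rule: correct unless some heterospecific hit is exactly 100%
    if (sum(names(species_of) != query & species_of == sp) > 0 && n_raw == 0) {
      stop("query_correct: query ", query,
           " absent from hit table but species has multiple accessions")
    }
    het <- h[!con, , drop = FALSE]
    return(!any(het$n_denom > 0 & het$n_ident == het$n_denom))
  }
  imax <- max(h$identity[con])
  het <- h$identity[!con]
  if (!length(het)) return(TRUE)
  xmax <- max(het)
  imax > xmax || (imax == xmax && cfg$tie_policy == "pass")
}

#' Per-species resolution status for one marker scope
#'
#' Classifies every species as IS (correctly identified), NIS (not
#' identified) or NA (no sequence available in the scope).
#'
#' @param lib a [ref_library()]; for reduced sampling pass the output of
#'   [reduced_library()].
#' @param hits hit table for `scope` (complete matrix).
#' @param cfg a [resolution_config()].
#' @param scope a marker id or `"combined"`; defaults to the first entry of
#'   `cfg$markers`.
#' @param all_species optional character vector of the full species universe;
#'   species absent from `lib` are reported with status `"NA"` (used to keep
#'   reduced-sampling summaries on the complete species total).
#' @return data.frame with `species`, `marker_scope`, `status`,
#'   `n_accessions`.
#' @export
species_status <- function(lib, hits, cfg = resolution_config(),
                           scope = cfg$markers[[1]], all_species = NULL) {
  stopifnot(inherits(lib, "ref_library"))
  rec <- lib$records
  in_scope <- if (identical(scope, "combined")) rep(TRUE, nrow(rec)) else rec$marker_id == scope
  srec <- unique(rec[in_scope, c("specimen_id", "species")])
  species_of <- setNames(srec$species, srec$specimen_id)
  species <- sort(unique(c(rec$species, all_species)))
  status <- character(length(species))
  n_acc <- integer(length(species))
  for (k in seq_along(species)) {
    sp <- species[k]
    ids <- srec$specimen_id[srec$species == sp]
    n_acc[k] <- length(ids)
    if (!length(ids)) {
      status[k] <- "NA"
    } else {
      ok <- vapply(ids, query_correct, logical(1),
                   hits = hits, species_of = species_of, cfg = cfg)
      status[k] <- if (cfg$aggregation == "all_queries") {
        if (all(ok)) "IS" else "NIS"
      } else {
        if (any(ok)) "IS" else "NIS"
      }
    }
  }
  data.frame(species = species, marker_scope = scope, status = status,
             n_accessions = n_acc, row.names = NULL)
}

# half-up rounding to 2 decimals (the convention the printed summary tables
# follow); the 1e-9 nudge guards against binary representation artifacts
round2 <- function(x) floor(x * 100 + 0.5 + 1e-9) / 100

#' Resolution summary statistics
#'
#' Builds the summary block of a barcode-resolution table: counts of
#' correctly identified (IS), non-identified (NIS) and sequence-less (NA)
#' species with the derived percentages, plus an optional phylogenetic block
#' (SSA, SMA, MS, NMS).
#'
#' @param statuses data.frame from [species_status()] covering every species
#'   in scope exactly once.
#' @param phylo optional list/vector with elements `SSA`, `SMA`, `MS`, `NMS`
#'   (e.g. from [phylo_summary()]).
#' @return One-row data.frame with columns `marker`, `IS`, `NIS`, `n_NA`,
#'   `pct_IS`, `pct_SS`, `SSA`, `SMA`, `MS`, `NMS`, `pct_SMA`, `pct_MS`.
#'   Percentages are half-up rounded to 2 decimals:
#'   `pct_IS = 100 IS / (IS + NIS)`, `pct_SS = 100 (IS + NIS) / total`,
#'   `pct_SMA = 100 SMA / (IS + NIS)`, `pct_MS = 100 MS / SMA` (reported as
#'   `NA` when `SMA = 0`).
#' @export
resolution_summary <- function(statuses, phylo = NULL) {
  if (anyDuplicated(statuses$species)) {
    stop("resolution_summary: duplicated species in statuses")
  }
  IS <- sum(statuses$status == "IS")
  NIS <- sum(statuses$status == "NIS")
  nNA <- sum(statuses$status == "NA")
  total <- IS + NIS + nNA
  stopifnot(total == nrow(statuses))  # conservation: IS + NIS + NA = species in scope
  out <- data.frame(
    marker = if (nrow(statuses)) statuses$marker_scope[1] else NA_character_,
    IS = IS, NIS = NIS, n_NA = nNA,
    pct_IS = if (IS + NIS > 0) round2(100 * IS / (IS + NIS)) else NA_real_,
    pct_SS = if (total > 0) round2(100 * (IS + NIS) / total) else NA_real_,
    SSA = NA_integer_, SMA = NA_integer_, MS = NA_integer_, NMS = NA_integer_,
    pct_SMA = NA_real_, pct_MS = NA_real_,
    row.names = NULL
  )
  if (!is.null(phylo)) {
    phylo <- as.list(phylo)
    stopifnot(all(c("SSA", "SMA", "MS", "NMS") %in% names(phylo)))
    out$SSA <- as.integer(phylo$SSA)
    out$SMA <- as.integer(phylo$SMA)
    out$MS <- as.integer(phylo$MS)
    out$NMS <- as.integer(phylo$NMS)
    stopifnot(out$MS + out$NMS == out$SMA)
    if (IS + NIS > 0) out$pct_SMA <- round2(100 * out$SMA / (IS + NIS))
    out$pct_MS <- if (out$SMA > 0) round2(100 * out$MS / out$SMA) else NA_real_
  }
  out
}

#' Novelty of a species set against an external checklist
#'
#' Plain set arithmetic: how many library species are absent from a provided
#' external species set (e.g. a download of previously barcoded species).
#' No remote lookup is performed.
#'
#' @param lib_species character vector of library species.
#' @param external_species character vector of externally known species.
#' @return List with `n_new` and `n_known`.
#' @export
novelty_report <- function(lib_species, external_species) {
  lib_species <- unique(lib_species)
  list(n_new = length(setdiff(lib_species, external_species)),
       n_known = length(intersect(lib_species, external_species)))
}

#' Full resolution table over marker scopes and samplings
#'
#' Runs the decision rule for every marker and the combined scope, under
#' complete and (optionally) reduced sampling, reproducing the standard
#' six-matrix design for a two-marker library.
#'
#' @param lib a [ref_library()].
#' @param markers markers to analyse (default: all library markers).
#' @param include_combined also analyse the pooled "combined" scope.
#' @param include_reduced also analyse the reduced sampling (species with all
#'   `markers`).
#' @param cfg a [resolution_config()] (tie policy / aggregation).
#' @param scoring an [align_scoring()].
#' @param all_species optional full species universe (default: library
#'   species); reduced-sampling rows count species outside the reduced
#'   library as NA against this universe.
#' @param phylo_blocks optional named list: scope name (e.g. `"rbcL"`,
#'   `"combined_reduced"`) to a list with `SSA`, `SMA`, `MS`, `NMS`.
#' @return List with `summary` (one row per scope) and `statuses` (per-species
#'   status tables, named by scope).
#' @export
resolution_table <- function(lib, markers = lib$markers, include_combined = TRUE,
                             include_reduced = TRUE, cfg = resolution_config(),
                             scoring = align_scoring(), all_species = NULL,
                             phylo_blocks = NULL) {
  stopifnot(inherits(lib, "ref_library"))
  if (is.null(all_species)) all_species <- unique(lib$records$species)
  hits <- lapply(setNames(markers, markers), function(m) {
    suppressWarnings(all_pairs_identity(lib, m, scoring))
  })
  scopes <- list()
  for (m in markers) {
    scopes[[m]] <- list(lib = lib, hits = hits[[m]], scope = m)
  }
  if (include_combined && length(markers) > 1) {
    scopes[["combined"]] <- list(lib = lib, hits = combine_hits(hits), scope = "combined")
  }
  if (include_reduced) {
    red <- reduced_library(lib, markers)
    red_ids <- unique(red$records$specimen_id)
    # reduced-scope hits are a subset of the complete matrices: no realignment
    red_hits <- lapply(hits, function(h) {
      h[h$query_id %in% red_ids & h$subject_id %in% red_ids, , drop = FALSE]
    })
    for (m in markers) {
      scopes[[paste0(m, "_reduced")]] <- list(lib = red, hits = red_hits[[m]], scope = m)
    }
    if (include_combined && length(markers) > 1) {
      scopes[["combined_reduced"]] <-
        list(lib = red, hits = combine_hits(red_hits), scope = "combined")
    }
  }
  statuses <- list()
  rows <- list()
  for (nm in names(scopes)) {
    sc <- scopes[[nm]]
    st <- species_status(sc$lib, sc$hits, cfg, scope = sc$scope,
                         all_species = all_species)
    st$marker_scope <- nm
    statuses[[nm]] <- st
    rows[[nm]] <- resolution_summary(st, phylo = phylo_blocks[[nm]])
  }
  list(summary = do.call(rbind, rows), statuses = statuses)
}

#' Write a resolution summary as TSV (and optionally JSON)
#'
#' Columns mirror the conventional table order: Marker, IS, NIS, NA, \%IS,
#' \%SS, SSA, SMA, MS, NMS, \%SMA, \%MS.
#'
#' @param summary data.frame from [resolution_summary()] / [resolution_table()].
#' @param path TSV output path.
#' @param json_path optional JSON output path.
#' @return Invisibly, `path`.
#' @export
write_resolution_summary <- function(summary, path, json_path = NULL) {
  out <- summary
  names(out) <- c("Marker", "IS", "NIS", "NA", "%IS", "%SS", "SSA", "SMA",
                  "MS", "NMS", "%SMA", "%MS")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "-")
  if (!is.null(json_path)) {
    jsonlite::write_json(summary, json_path, dataframe = "rows", na = "null",
                         digits = NA)
  }
  invisible(path)
}
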