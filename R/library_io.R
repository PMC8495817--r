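# Reference library container and readers/writers.
#
# A library is a flat specimen x marker record table joined to a ranked
# taxonomy (species -> genus -> family -> order).  Sequences are IUPAC DNA,
# stored uppercase; (specimen_id, marker_id) is unique.

.IUPAC <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

.TAX_COLS <- c("specimen_id", "species", "genus", "family", "order")
.REC_COLS <- c("specimen_id", "marker_id", "sequence", .TAX_COLS[-1])

#' Construct a reference barcode library
#'
#' @param records data.frame with columns `specimen_id`, `marker_id`,
#'   `sequence`, `species`, `genus`, `family`, `order`.  Sequences are
#'   uppercased and validated against the IUPAC nucleotide alphabet.
#' @param markers ordered character vector of marker ids; defaults to the
#'   markers present in `records`, in order of first appearance.
#'
#' @return An object of class `ref_library`: a list with elements `records`
#'   (the validated record table) and `markers`.
#'
#' @details Validation enforces the type invariants: non-empty IUPAC
#'   sequences, unique (specimen, marker) pairs, every record marker among
#'   `markers`, and a consistent ranked taxonomy (each species under exactly
#'   one genus, each genus under one family, each family under one order).
#'
#' @examples
#' rec <- data.frame(
#'   specimen_id = c("s1", "s2"), marker_id = "rbcL",
#'   sequence = c("acgt", "ACGA"), species = c("A x", "B y"),
#'   genus = c("A", "B"), family = c("F", "F"), order = c("O", "O")
#' )
#' lib <- ref_library(rec)
#' library_counts(lib)$n_species
#' @export
ref_library <- function(records, markers = NULL) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.REC_COLS, names(records))
  if (length(missing_cols)) {
    stop("records lack required columns: ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, .REC_COLS]
  for (col in .REC_COLS) records[[col]] <- as.character(records[[col]])

  if (nrow(records)) {
    records$sequence <- toupper(records$sequence)
    if (any(!nzchar(records$sequence))) stop("empty sequence in records")
    bad <- vapply(strsplit(records$sequence, ""),
                  function(s) any(!s %in% .IUPAC), logical(1))
    if (any(bad)) {
      stop("non-IUPAC characters in sequence(s) of: ",
           paste(utils::head(records$specimen_id[bad], 5), collapse = ", "))
    }
    key <- paste(records$specimen_id, records$marker_id, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1]
      stop("duplicate (specimen, marker) record: ", sub("\r", " / ", d))
    }
    .check_rank_consistency(records)
  }

  if (is.null(markers)) markers <- unique(records$marker_id)
  markers <- as.character(markers)
  if (nrow(records) && !all(records$marker_id %in% markers)) {
    stop("record marker(s) not in declared marker set")
  }

  structure(list(records = records, markers = markers), class = "ref_library")
}

.check_rank_consistency <- function(tax) {
  pairs <- list(c("species", "genus"), c("genus", "family"), c("family", "order"))
  for (p in pairs) {
    u <- unique(tax[, p])
    dup <- u[[1]][duplicated(u[[1]])]
    if (length(dup)) {
      stop("taxonomy rank conflict: ", p[1], " '", dup[1], "' assigned to multiple ",
           p[2], " values (", paste(u[[2]][u[[1]] == dup[1]], collapse = ", "), ")")
    }
  }
  invisible(TRUE)
}

#' @export
print.ref_library <- function(x, ...) {
  cnt <- library_counts(x)
  cat("Reference barcode library\n")
  cat(sprintf("  %d records | %d specimens | %d species | markers: %s\n",
              cnt$n_barcodes, cnt$n_specimens, cnt$n_species,
              paste(x$markers, collapse = ", ")))
  invisible(x)
}

#' Read a reference library from FASTA files and a taxonomy table
#'
#' @param sequence_files named character vector of FASTA paths; names are
#'   marker ids (e.g. `c(rbcL = "rbcL.fasta", ITS2 = "ITS2.fasta")`).
#' @param taxonomy_file path to a tab-delimited taxonomy table with header
#'   columns `specimen_id`, `species`, `genus`, `family`, `order`.
#'
#' @return A [ref_library()].
#'
#' @details FASTA record ids (the first whitespace-delimited token of each
#'   header) must be specimen ids present in the taxonomy table; an unknown
#'   id, a duplicated (specimen, marker) record, or a rank conflict in the
#'   taxonomy is a fatal error naming the offender.
#' @export
read_library <- function(sequence_files, taxonomy_file) {
  if (is.null(names(sequence_files)) || any(!nzchar(names(sequence_files)))) {
    stop("sequence_files must be a named vector (names are marker ids)")
  }
  tax <- read.delim(taxonomy_file, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.TAX_COLS, names(tax))
  if (length(missing_cols)) {
    stop("taxonomy table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tax$specimen_id)) {
    stop("duplicate specimen_id in taxonomy table: ",
         tax$specimen_id[duplicated(tax$specimen_id)][1])
  }
  rec_list <- lapply(names(sequence_files), function(mk) {
    ss <- Biostrings::readDNAStringSet(sequence_files[[mk]])
    ids <- sub("\\s.*$", "", names(ss))
    unknown <- setdiff(ids, tax$specimen_id)
    if (length(unknown)) {
      stop("FASTA record(s) not in taxonomy table (marker ", mk, "): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    idx <- match(ids, tax$specimen_id)
    data.frame(specimen_id = ids, marker_id = mk,
               sequence = as.character(ss),
               species = tax$species[idx], genus = tax$genus[idx],
               family = tax$family[idx], order = tax$order[idx],
               row.names = NULL)
  })
  ref_library(do.call(rbind, rec_list), markers = names(sequence_files))
}

#' Write a reference library as per-marker FASTA plus a taxonomy TSV
#'
#' Records are written in deterministic order (specimen id, then marker id).
#'
#' @param lib a [ref_library()].
#' @param dir output directory (created if absent).
#' @return Invisibly, the paths written (per-marker FASTA and `taxonomy.tsv`).
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "ref_library"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- lib$records[order(lib$records$specimen_id, lib$records$marker_id), ]
  paths <- character(0)
  for (mk in lib$markers) {
    sub <- rec[rec$marker_id == mk, ]
    p <- file.path(dir, paste0(mk, ".fasta"))
    ss <- Biostrings::DNAStringSet(setNames(sub$sequence, sub$specimen_id))
    Biostrings::writeXStringSet(ss, p)
    paths <- c(paths, p)
  }
  tax <- unique(rec[, .TAX_COLS])
  tax <- tax[order(tax$specimen_id), ]
  tp <- file.path(dir, "taxonomy.tsv")
  write.table(tax, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tp))
}

#' Summary counts for a reference library
#'
#' @param lib a [ref_library()].
#' @return A list with `n_specimens`, `n_species`, `n_genera`, `n_families`,
#'   `n_barcodes`, `per_marker` (data.frame of records and species per
#'   marker), and `n_species_all_markers` (species having every marker of the
#'   library).  An empty library yields all-zero counts.
#' @export
library_counts <- function(lib) {
  stopifnot(inherits(lib, "ref_library"))
  rec <- lib$records
  per_marker <- data.frame(
    marker_id = lib$markers,
    n_records = vapply(lib$markers, function(m) sum(rec$marker_id == m), integer(1)),
    n_species = vapply(lib$markers, function(m) length(unique(rec$species[rec$marker_id == m])), integer(1)),
    row.names = NULL
  )
  sp_all <- if (length(lib$markers) && nrow(rec)) {
    Reduce(intersect, lapply(lib$markers, function(m) unique(rec$species[rec$marker_id == m])))
  } else {
    character(0)
  }
  list(
    n_specimens = length(unique(rec$specimen_id)),
    n_species = length(unique(rec$species)),
    n_genera = length(unique(rec$genus)),
    n_families = length(unique(rec$family)),
    n_barcodes = nrow(rec),
    per_marker = per_marker,
    n_species_all_markers = length(sp_all)
  )
}

#' Restrict a library to species covered by all required markers
#'
#' Mirrors the "reduced sampling" of combined-marker analyses: only species
#' having at least one sequence of every required marker are retained (all of
#' their records, for all markers, are kept).
#'
#' @param lib a [ref_library()].
#' @param required_markers character vector of marker ids; an empty vector
#'   returns the library unchanged.
#' @return A [ref_library()] with the same marker set.
#' @export
reduced_library <- function(lib, required_markers) {
  stopifnot(inherits(lib, "ref_library"))
  required_markers <- as.character(required_markers)
  unknown <- setdiff(required_markers, lib$markers)
  if (length(unknown)) stop("unknown marker(s): ", paste(unknown, collapse = ", "))
  if (!length(required_markers)) return(lib)
  rec <- lib$records
  keep_sp <- Reduce(intersect, lapply(required_markers, function(m) {
    unique(rec$species[rec$marker_id == m])
  }))
  ref_library(rec[rec$species %in% keep_sp, , drop = FALSE], markers = lib$markers)
}

#' Specimen-to-species lookup for a library
#'
#' @param lib a [ref_library()].
#' @return Named character vector mapping specimen ids to species names.
#' @export
species_map <- function(lib) {
  stopifnot(inherits(lib, "ref_library"))
  u <- unique(lib$records[, c("specimen_id", "species")])
  setNames(u$species, u$specimen_id)
}

#' Species-level taxonomy of a library
#'
#' @param lib a [ref_library()].
#' @return data.frame with one row per species: `species`, `genus`, `family`,
#'   `order`.
#' @export
species_taxonomy <- function(lib) {
  stopifnot(inherits(lib, "ref_library"))
  u <- unique(lib$records[, c("species", "genus", "family", "order")])
  u[order(u$species), , drop = FALSE]
}
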