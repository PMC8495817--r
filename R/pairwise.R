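# Pairwise semi-global alignment, percent identity and query coverage.
#
# Identity is computed over the overlap region of the alignment: all columns
# except those where either row carries a terminal (leading/trailing) gap.
# Internal gap columns count in the denominator; an ambiguity code matches
# only the exact same symbol.  Coverage is the fraction of query residues
# lying inside the overlap region.  Decision rules downstream compare
# identities as exact (identical, denominator) integer pairs.

#' Alignment scoring scheme
#'
#' Blastn-like defaults for semi-global (ends-free) alignment.  A gap run of
#' length L costs `gap_open + L * gap_extend`; terminal gaps are free.
#'
#' @param match positive match score.
#' @param mismatch mismatch score (<= 0).
#' @param gap_open gap opening penalty (<= 0), paid once per internal gap run.
#' @param gap_extend gap extension penalty (<= 0), paid per gap column.
#' @return An object of class `align_scoring`.
#' @export
align_scoring <- function(match = 2L, mismatch = -3L, gap_open = -5L, gap_extend = -2L) {
  match <- as.integer(match); mismatch <- as.integer(mismatch)
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 mode = "semi-global"),
            class = "align_scoring")
}

#' Optimal semi-global alignment of two sequences
#'
#' Full dynamic programming (no heuristics).  Ties are resolved
#' deterministically: maximal score, then fewest internal gap columns, then a
#' fixed traceback preference (substitution over gap-in-subject over
#' gap-in-query; endpoints prefer the longest overlap).
#'
#' @param a query sequence (character scalar, IUPAC DNA).
#' @param b subject sequence.
#' @param scoring an [align_scoring()].
#' @return A list of class `pairwise_alignment` with gapped `query` and
#'   `subject` strings and the integer `score`.
#' @examples
#' aln <- align_pair("ACGT", "TTACGTTT")
#' identity_and_coverage(aln, query_length = 4L)
#' @export
align_pair <- function(a, b, scoring = align_scoring()) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("align_pair: empty input sequence")
  r <- align_pair_cpp(toupper(a), toupper(b), scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  structure(r, class = "pairwise_alignment")
}

# overlap-region statistics of a gapped pair (internal)
alignment_stats <- function(alignment) {
  qa <- strsplit(alignment$query, "")[[1]]
  sa <- strsplit(alignment$subject, "")[[1]]
  resq <- which(qa != "-"); ress <- which(sa != "-")
  if (!length(resq) || !length(ress)) {
    return(list(n_ident = 0L, n_denom = 0L, q_res = 0L))
  }
  lo <- max(min(resq), min(ress)); hi <- min(max(resq), max(ress))
  if (lo > hi) return(list(n_ident = 0L, n_denom = 0L, q_res = 0L))
  qa <- qa[lo:hi]; sa <- sa[lo:hi]
  list(n_ident = sum(qa != "-" & qa == sa),
       n_denom = hi - lo + 1L,
       q_res = sum(qa != "-"))
}

#' Percent identity and query coverage of an alignment
#'
#' @param alignment a `pairwise_alignment` from [align_pair()].
#' @param query_length ungapped length of the query sequence.
#' @return Named numeric vector `c(identity, coverage)` in percent.  An
#'   alignment with an empty overlap region (fully non-overlapping sequences)
#'   yields identity 0 and coverage 0.
#' @export
identity_and_coverage <- function(alignment, query_length) {
  st <- alignment_stats(alignment)
  identity <- if (st$n_denom > 0) 100 * st$n_ident / st$n_denom else 0
  c(identity = identity, coverage = 100 * st$q_res / query_length)
}

#' Alignment statistics for a sequence pair
#'
#' Convenience wrapper returning the exact integer counts the decision rules
#' operate on, along with derived percentages.
#'
#' @inheritParams align_pair
#' @return List with `n_ident`, `n_denom`, `q_res`, `score`, `identity`,
#'   `coverage` (coverage is with respect to `a`, the query).
#' @export
pair_stats <- function(a, b, scoring = align_scoring()) {
  stopifnot(is.character(a), length(a) == 1L, is.character(b), length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("pair_stats: empty input sequence")
  v <- pair_stats_cpp(toupper(a), toupper(b), scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  list(n_ident = v[["n_ident"]], n_denom = v[["n_denom"]], q_res = v[["q_res"]],
       score = v[["score"]],
       identity = if (v[["n_denom"]] > 0) 100 * v[["n_ident"]] / v[["n_denom"]] else 0,
       coverage = 100 * v[["q_res"]] / nchar(a))
}

#' All-to-all pairwise identity for one marker
#'
#' Computes the complete identity matrix for all records of a marker: one hit
#' per unordered specimen pair, self-hits excluded.  This subsumes a
#' top-hits-only search, since the decision rule needs maxima over
#' conspecific and heterospecific hit sets.
#'
#' @param lib a [ref_library()].
#' @param marker marker id to compare.
#' @param scoring an [align_scoring()].
#' @return data.frame of hits: `query_id`, `subject_id`, `marker_scope`,
#'   `identity`, `coverage` (of the query), `aligned_columns`, and the exact
#'   counts `n_ident`, `n_denom`, `n_qres`, `query_length`, `subject_length`.
#'   Fewer than two records yields an empty table with a warning.
#' @export
all_pairs_identity <- function(lib, marker, scoring = align_scoring()) {
  stopifnot(inherits(lib, "ref_library"))
  if (!marker %in% lib$markers) stop("unknown marker: ", marker)
  rec <- lib$records[lib$records$marker_id == marker, , drop = FALSE]
  if (nrow(rec) < 2) {
    warning("all_pairs_identity: fewer than 2 records for marker ", marker)
    return(.empty_hits())
  }
  m <- all_pairs_stats_cpp(rec$sequence, scoring$match, scoring$mismatch,
                           scoring$gap_open, scoring$gap_extend)
  qlen <- nchar(rec$sequence)
  data.frame(
    query_id = rec$specimen_id[m[, "i"]],
    subject_id = rec$specimen_id[m[, "j"]],
    marker_scope = marker,
    identity = ifelse(m[, "n_denom"] > 0, 100 * m[, "n_ident"] / m[, "n_denom"], 0),
    coverage = 100 * m[, "q_res"] / qlen[m[, "i"]],
    aligned_columns = m[, "n_denom"],
    n_ident = m[, "n_ident"],
    n_denom = m[, "n_denom"],
    n_qres = m[, "q_res"],
    query_length = qlen[m[, "i"]],
    subject_length = qlen[m[, "j"]],
    row.names = NULL
  )
}

.empty_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             marker_scope = character(0), identity = numeric(0),
             coverage = numeric(0), aligned_columns = integer(0),
             n_ident = integer(0), n_denom = integer(0), n_qres = integer(0),
             query_length = integer(0), subject_length = integer(0))
}

#' Pool per-marker hits into combined-marker hits
#'
#' For every specimen pair sharing at least one marker, identical and
#' denominator columns are summed across the shared markers and the pooled
#' identity is `100 * sum(identical) / sum(denominator)`.  Pairs sharing no
#' marker are absent from the result (excluded, not an error).
#'
#' @param hits_list list of per-marker hit tables from [all_pairs_identity()].
#' @return data.frame of hits with `marker_scope = "combined"`.
#' @export
combine_hits <- function(hits_list) {
  stopifnot(is.list(hits_list), length(hits_list) >= 1)
  all <- do.call(rbind, hits_list)
  if (!nrow(all)) return(.empty_hits())
  # canonical unordered pair key; identity is symmetric so pooling n_ident and
  # n_denom needs no orientation bookkeeping.  Pooled coverage is reported with
  # respect to the stored query orientation of each component hit (the decision
  # rules use identity only; coverage asymmetry is documented).
  key <- paste(pmin(all$query_id, all$subject_id),
               pmax(all$query_id, all$subject_id), sep = "\r")
  agg <- function(x) as.vector(rowsum(x, key, reorder = TRUE))
  keys <- sort(unique(key))
  n_ident <- agg(all$n_ident)
  n_denom <- agg(all$n_denom)
  n_qres <- agg(all$n_qres)
  qlen_sum <- agg(all$query_length)
  data.frame(
    query_id = sub("\r.*$", "", keys),
    subject_id = sub("^.*\r", "", keys),
    marker_scope = "combined",
    identity = ifelse(n_denom > 0, 100 * n_ident / n_denom, 0),
    coverage = 100 * n_qres / qlen_sum,
    aligned_columns = n_denom,
    n_ident = n_ident,
    n_denom = n_denom,
    n_qres = n_qres,
    query_length = qlen_sum,
    subject_length = agg(all$subject_length),
    row.names = NULL
  )
}

#' Combined-marker identity for one specimen pair
#'
#' Aligns each marker shared by the two specimens and pools identical and
#' denominator columns across markers.
#'
#' @param lib a [ref_library()].
#' @param specimen_a,specimen_b specimen ids.
#' @param markers ordered marker set to pool over (default: all library markers).
#' @param scoring an [align_scoring()].
#' @return A one-row hit data.frame (`marker_scope = "combined"`), or `NULL`
#'   (with a message) when the specimens share no marker.
#' @export
combined_identity <- function(lib, specimen_a, specimen_b,
                              markers = lib$markers, scoring = align_scoring()) {
  stopifnot(inherits(lib, "ref_library"))
  rec <- lib$records
  n_ident <- 0L; n_denom <- 0L; n_qres <- 0L; qlen <- 0L; slen <- 0L
  shared <- 0L
  for (mk in markers) {
    sa <- rec$sequence[rec$specimen_id == specimen_a & rec$marker_id == mk]
    sb <- rec$sequence[rec$specimen_id == specimen_b & rec$marker_id == mk]
    if (length(sa) == 1 && length(sb) == 1) {
      shared <- shared + 1L
      st <- pair_stats(sa, sb, scoring)
      n_ident <- n_ident + st$n_ident
      n_denom <- n_denom + st$n_denom
      n_qres <- n_qres + st$q_res
      qlen <- qlen + nchar(sa)
      slen <- slen + nchar(sb)
    }
  }
  if (shared == 0L) {
    message("combined_identity: specimens ", specimen_a, " and ", specimen_b,
            " share no marker; pair excluded")
    return(NULL)
  }
  data.frame(query_id = specimen_a, subject_id = specimen_b,
             marker_scope = "combined",
             identity = if (n_denom > 0) 100 * n_ident / n_denom else 0,
             coverage = 100 * n_qres / qlen,
             aligned_columns = n_denom, n_ident = n_ident, n_denom = n_denom,
             n_qres = n_qres, query_length = qlen, subject_length = slen,
             row.names = NULL)
}

#' Write a hit table as TSV
#'
#' @param hits a hit data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_hits <- function(hits, path) {
  cols <- c("query_id", "subject_id", "marker_scope", "identity", "coverage",
            "aligned_columns")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
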