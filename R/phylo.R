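# Supported-monophyly counting on specimen trees, plus a neighbor-joining +
# nonparametric bootstrap stand-in tree builder so the pipeline runs end to
# end without an external maximum-likelihood inference.
#
# Monophyly is defined on unrooted bipartitions: a species is monophyletic
# iff some bipartition of the tree separates exactly its tip set from all
# other tips.  Bootstrap supports are read off internal node labels.

#' Configuration for phylogenetic resolution
#'
#' @param min_support minimum bootstrap support (percent) for a monophyletic
#'   species to count as resolved (default 70).
#' @param n_bootstrap number of bootstrap replicates for
#'   [bootstrap_supports()] (default 1000; reducible).
#' @param seed integer seed for the bootstrap resampling.
#' @return An object of class `phylo_config`.
#' @export
phylo_config <- function(min_support = 70, n_bootstrap = 1000L, seed = 1L) {
  stopifnot(min_support >= 0, min_support <= 100)
  structure(list(min_support = min_support,
                 n_bootstrap = as.integer(n_bootstrap),
                 seed = as.integer(seed)),
            class = "phylo_config")
}

#' Read a newick tree with bootstrap supports as internal node labels
#'
#' @param path path to a newick file (supports encoded as internal node
#'   labels, e.g. `"((a1,a2)95,(b1,b2)80);"`).
#' @return An `ape` `phylo` object.  Missing supports are permitted (labels
#'   absent or empty); numeric labels must lie in \[0, 100\].
#' @export
read_newick_with_support <- function(path) {
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("unparsable newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("unparsable newick in ", path)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf label(s): ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  sup <- support_values(tr)
  bad <- !is.na(sup) & (sup < 0 | sup > 100)
  if (any(bad)) stop("support value(s) outside [0, 100]")
  tr
}

#' Write a tree, keeping supports as internal node labels
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_newick_with_support <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Numeric support values of a tree's internal nodes
#'
#' @param tree a `phylo` object.
#' @return Numeric vector of length `tree$Nnode` (NA where absent).
#' @export
support_values <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!nzchar(trimws(ifelse(is.na(tree$node.label), "", tree$node.label)))] <- NA
  sup
}

#' Species monophyly with bootstrap support
#'
#' For each species with two or more tips, tests whether some bipartition of
#' the unrooted tree separates exactly its tip set, and reads that
#' bipartition's support.  Singleton species are reported with
#' `n_tips = 1` and enter the summary as SSA.
#'
#' @param tree a `phylo` with specimen tip labels and supports as node
#'   labels (see [read_newick_with_support()]).
#' @param species_of named character vector mapping every tip label to its
#'   species (e.g. [species_map()]).
#' @param cfg a [phylo_config()] (only `min_support` is used).
#' @return data.frame with `species`, `n_tips`, `is_monophyletic` (NA for
#'   singletons), `support` (NA when the separating edge carries no label,
#'   e.g. a pendant edge), `counted_as_MS`.
#' @details Tips attached to one polytomy without an exclusive edge have no
#'   separating bipartition and are non-monophyletic.  A species covering all
#'   tips, or all but one, is separated only by the root/pendant edge, which
#'   carries no bootstrap label: such species are monophyletic with support
#'   NA (and therefore never counted as MS).
#' @export
species_monophyly <- function(tree, species_of, cfg = phylo_config()) {
  tips <- tree$tip.label
  sp <- unname(species_of[tips])
  if (any(is.na(sp))) {
    stop("leaf/leaves without species mapping: ",
         paste(utils::head(tips[is.na(sp)], 5), collapse = ", "))
  }
  ntip <- length(tips)
  sup <- support_values(tree)
  # clade tip sets per internal node; a species separated by an internal edge
  # appears either as a clade (its own tip set) or as a clade's complement
  # (both sides of one unrooted bipartition).  When both representations
  # exist -- the two children of a dichotomous root -- the clade matching the
  # species' own tip set carries its support.
  parts <- ape::prop.part(tree)
  keyof <- function(v) paste(sort(v), collapse = ",")
  clade_key <- vapply(parts, keyof, character(1))
  comp_key <- vapply(parts, function(v) keyof(setdiff(seq_len(ntip), v)),
                     character(1))
  is_root <- lengths(parts) == ntip
  species <- sort(unique(sp))
  res <- data.frame(species = species, n_tips = 0L, is_monophyletic = NA,
                    support = NA_real_, counted_as_MS = FALSE)
  for (i in seq_along(species)) {
    tv <- which(sp == species[i])
    res$n_tips[i] <- length(tv)
    if (length(tv) < 2L) next
    if (length(tv) == ntip) {
      # the whole tip set: trivially monophyletic, no separating edge
      res$is_monophyletic[i] <- TRUE
      res$support[i] <- NA_real_
    } else if (length(tv) == ntip - 1L) {
      # separated by the excluded tip's pendant edge: always monophyletic;
      # a support exists only when the rooted form exposes this clade
      res$is_monophyletic[i] <- TRUE
      hit <- which(!is_root & clade_key == keyof(tv))
      res$support[i] <- if (length(hit)) sup[hit[1]] else NA_real_
    } else {
      key <- keyof(tv)
      hit <- which(!is_root & clade_key == key)
      if (!length(hit)) hit <- which(!is_root & comp_key == key)
      res$is_monophyletic[i] <- length(hit) > 0
      res$support[i] <- if (length(hit)) sup[hit[1]] else NA_real_
    }
    res$counted_as_MS[i] <- isTRUE(res$is_monophyletic[i]) &&
      !is.na(res$support[i]) && res$support[i] >= cfg$min_support
  }
  res
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper over [ape::nj()] used as the pipeline's stand-in tree
#' builder; negative branch lengths are clamped to zero.
#'
#' @param d symmetric nonnegative distance matrix (or `dist`) with a zero
#'   diagonal, labelled by specimen ids.
#' @return A `phylo` object (no supports).
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3) stop("nj_tree: need at least 3 taxa")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)) || any(diag(m) != 0) || any(m < 0)) {
    stop("nj_tree: distance matrix must be symmetric, nonnegative, zero-diagonal")
  }
  tr <- ape::nj(m)
  tr$edge.length <- pmax(tr$edge.length, 0)
  tr
}

# exact-match p-distance between aligned rows; any symbol matches only itself
p_distance <- function(aln) {
  stopifnot(is.matrix(aln), ncol(aln) >= 1)
  L <- ncol(aln)
  matches <- matrix(0, nrow(aln), nrow(aln))
  for (s in unique(as.vector(aln))) {
    I <- (aln == s) * 1
    matches <- matches + tcrossprod(I)
  }
  d <- (L - matches) / L
  diag(d) <- 0
  dimnames(d) <- list(rownames(aln), rownames(aln))
  d
}

#' Nonparametric bootstrap supports for a distance-based tree
#'
#' Builds a tree from the full alignment with `builder`, then resamples
#' alignment columns with replacement `n_bootstrap` times, rebuilds, and
#' labels each internal node of the original tree with the percentage of
#' replicates containing its bipartition.
#'
#' @param aln character matrix (rows = specimens, equal-length aligned
#'   columns) or named character vector of equal-length sequences.
#' @param builder function from distance matrix to `phylo` (default
#'   [nj_tree()]).
#' @param cfg a [phylo_config()]; `n_bootstrap` and `seed` are used.
#' @return The original tree with `node.label` set to supports (percent).
#' @export
bootstrap_supports <- function(aln, builder = nj_tree, cfg = phylo_config()) {
  if (!is.matrix(aln)) {
    stopifnot(is.character(aln), !is.null(names(aln)))
    if (length(unique(nchar(aln))) != 1) {
      stop("bootstrap_supports: sequences must be aligned (equal length)")
    }
    nm <- names(aln)
    aln <- do.call(rbind, strsplit(unname(aln), ""))
    rownames(aln) <- nm
  }
  if (is.null(rownames(aln))) stop("bootstrap_supports: rows must be named")
  if (nrow(aln) < 3) stop("bootstrap_supports: need at least 3 specimens")
  if (cfg$n_bootstrap <= 0) stop("bootstrap_supports: n_bootstrap must be positive")
  main <- builder(p_distance(aln))
  set.seed(cfg$seed)
  boots <- vector("list", cfg$n_bootstrap)
  for (b in seq_len(cfg$n_bootstrap)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    boots[[b]] <- builder(p_distance(aln[, cols, drop = FALSE]))
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- as.character(round(100 * counts / cfg$n_bootstrap, 2))
  main
}

#' Phylogenetic resolution counts
#'
#' @param results data.frame from [species_monophyly()], one row per species
#'   (singletons included with `n_tips = 1`).
#' @return List with `SSA` (single-accession species), `SMA` (multi-accession
#'   species), `MS` (monophyletic with support at or above the threshold) and
#'   `NMS = SMA - MS`.
#' @export
phylo_summary <- function(results) {
  stopifnot(!anyDuplicated(results$species))
  SMA <- sum(results$n_tips >= 2L)
  MS <- sum(results$counted_as_MS)
  list(SSA = sum(results$n_tips == 1L), SMA = SMA, MS = MS, NMS = SMA - MS)
}
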