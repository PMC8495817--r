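# Synthetic reference libraries and bulk-sample ASV tables with ground truth.
#
# Sequences evolve under Jukes-Cantor on a rank-balanced tree (one root per
# marker; family -> genus -> species -> specimen branches).  JC is the
# simplest model with a closed-form identity expectation, which is what the
# generator is for: structural ground truth, not realism.  Along a path of
# total expected length d (substitutions/site) the probability that a site
# differs is (3/4) * (1 - exp(-4 d / 3)).

#' Marker profile for the sequence generator
#'
#' @param marker_id marker name (e.g. `"rbcL"`, `"ITS2"`).
#' @param base_length root sequence length (nt).
#' @param rate_multiplier relative substitution rate (1 = slow plastid-like).
#' @param indel_rate single-base indel events per site per unit branch length
#'   (used for the fast spacer-like marker; 0 keeps the marker pre-aligned).
#' @param missing_prob probability that a specimen lacks this marker.
#' @return An object of class `marker_profile`.
#' @export
marker_profile <- function(marker_id, base_length, rate_multiplier = 1,
                           indel_rate = 0, missing_prob = 0) {
  stopifnot(base_length > 0, rate_multiplier > 0, indel_rate >= 0,
            missing_prob >= 0, missing_prob <= 1)
  structure(list(marker_id = as.character(marker_id),
                 base_length = as.integer(base_length),
                 rate_multiplier = rate_multiplier,
                 indel_rate = indel_rate,
                 missing_prob = missing_prob),
            class = "marker_profile")
}

#' Default two-marker setup: slow plastid-like and fast nuclear-spacer-like
#'
#' The slow marker ("rbcL": 550 nt, rate 1, no indels, 12\% record
#' missingness) emulates a conserved coding plastid region; the fast marker
#' ("ITS2": 450 nt, rate 8, rare single-base indels, 15\% missingness)
#' emulates a rapidly evolving nuclear spacer.  The missingness levels put
#' the share of species carrying both markers near three quarters.
#'
#' @return List of two [marker_profile()] objects.
#' @export
default_markers <- function() {
  list(
    marker_profile("rbcL", base_length = 550L, rate_multiplier = 1,
                   indel_rate = 0, missing_prob = 0.12),
    marker_profile("ITS2", base_length = 450L, rate_multiplier = 8,
                   indel_rate = 0.01, missing_prob = 0.15)
  )
}

#' Configuration of the synthetic reference library
#'
#' Defaults emulate the singleton-rich sampling structure of a regional
#' flora barcoding campaign: about 62\% of species are represented by a
#' single specimen, the rest by 2-5.
#'
#' @param n_families number of families.
#' @param genera_per_family integer or integer range, genera drawn per family.
#' @param species_per_genus integer or integer range.
#' @param singleton_fraction probability a species has exactly one specimen.
#' @param specimens_per_species_range integer range for non-singleton species.
#' @param divergence named numeric: branch lengths (expected subs/site at
#'   rate 1) for `family`, `genus`, `species`, `intraspecific`; must be
#'   non-increasing in that order.
#' @param markers list of [marker_profile()] objects.
#' @param seed integer seed; every generator is a pure function of its
#'   configuration including the seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_families = 12L, genera_per_family = 2:4,
                       species_per_genus = 1:4, singleton_fraction = 0.62,
                       specimens_per_species_range = 2:5,
                       divergence = c(family = 0.10, genus = 0.05,
                                      species = 0.02, intraspecific = 0.002),
                       markers = default_markers(), seed = 1L) {
  stopifnot(n_families >= 1, all(genera_per_family >= 1),
            all(species_per_genus >= 1),
            singleton_fraction >= 0, singleton_fraction <= 1,
            all(specimens_per_species_range >= 2))
  stopifnot(all(c("family", "genus", "species", "intraspecific") %in% names(divergence)),
            all(divergence >= 0))
  d <- divergence[c("family", "genus", "species", "intraspecific")]
  if (any(diff(d) > 0)) {
    stop("divergence must be ordered family >= genus >= species >= intraspecific")
  }
  stopifnot(length(markers) >= 1,
            all(vapply(markers, inherits, logical(1), "marker_profile")))
  structure(list(n_families = as.integer(n_families),
                 genera_per_family = as.integer(genera_per_family),
                 species_per_genus = as.integer(species_per_genus),
                 singleton_fraction = singleton_fraction,
                 specimens_per_species_range = as.integer(specimens_per_species_range),
                 divergence = d, markers = markers, seed = as.integer(seed)),
            class = "sim_config")
}

#' Configuration of synthetic bulk samples
#'
#' Defaults emulate a small plot-based survey: six plots, a handful of
#' species per plot with lognormal read abundances, and occasional erroneous
#' daughter variants (few substitutions, low relative abundance, present only
#' where their parent is).
#'
#' @param n_plots number of bulk-sample plots.
#' @param species_per_plot integer range of species per plot.
#' @param abundance_lognormal_sigma sdlog of the per-species read counts.
#' @param error_asv_prob probability a true ASV spawns an erroneous daughter.
#' @param error_substitutions substitutions separating daughter from parent.
#' @param error_abundance_ratio daughter/parent per-sample count ratio (< 1).
#' @param marker_id marker the amplicon emulates (the fast marker).
#' @param seed integer seed.
#' @return An object of class `bulk_config`.
#' @export
bulk_config <- function(n_plots = 6L, species_per_plot = 8:15,
                        abundance_lognormal_sigma = 1,
                        error_asv_prob = 0.2, error_substitutions = 2L,
                        error_abundance_ratio = 0.1, marker_id = "ITS2",
                        seed = 1L) {
  stopifnot(n_plots >= 1, all(species_per_plot >= 1),
            abundance_lognormal_sigma >= 0,
            error_asv_prob >= 0, error_asv_prob <= 1,
            error_substitutions >= 1,
            error_abundance_ratio > 0, error_abundance_ratio < 1)
  structure(list(n_plots = as.integer(n_plots),
                 species_per_plot = as.integer(species_per_plot),
                 abundance_lognormal_sigma = abundance_lognormal_sigma,
                 error_asv_prob = error_asv_prob,
                 error_substitutions = as.integer(error_substitutions),
                 error_abundance_ratio = error_abundance_ratio,
                 marker_id = as.character(marker_id),
                 seed = as.integer(seed)),
            class = "bulk_config")
}

.draw_int <- function(rng) rng[sample.int(length(rng), 1L)]

#' Simulate a ranked taxonomy with singleton-rich specimen sampling
#'
#' @param cfg a [sim_config()].
#' @return data.frame with one row per specimen: `specimen_id`, `species`,
#'   `genus`, `family`, `order` (families are grouped pairwise into orders).
#'   Deterministic given `cfg$seed`.
#' @export
simulate_taxonomy <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rows <- list()
  for (f in seq_len(cfg$n_families)) {
    fam <- sprintf("F%02d", f)
    ord <- sprintf("O%02d", ceiling(f / 2))
    ng <- .draw_int(cfg$genera_per_family)
    for (g in seq_len(ng)) {
      gen <- sprintf("%s_G%02d", fam, g)
      ns <- .draw_int(cfg$species_per_genus)
      for (s in seq_len(ns)) {
        spp <- sprintf("%s_S%02d", gen, s)
        n_spec <- if (runif(1) < cfg$singleton_fraction) 1L
                  else .draw_int(cfg$specimens_per_species_range)
        for (i in seq_len(n_spec)) {
          rows[[length(rows) + 1L]] <- data.frame(
            specimen_id = sprintf("%s_%02d", spp, i),
            species = spp, genus = gen, family = fam, order = ord)
        }
      }
    }
  }
  if (!length(rows)) stop("simulate_taxonomy: zero taxa generated")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# exact JC transition applied to an integer-coded sequence over branch d
.jc_evolve <- function(seq_int, d) {
  if (d <= 0) return(seq_int)
  p <- 0.75 * (1 - exp(-4 * d / 3))
  hit <- runif(length(seq_int)) < p
  n <- sum(hit)
  if (n) {
    shift <- sample.int(3L, n, replace = TRUE)
    seq_int[hit] <- ((seq_int[hit] - 1L + shift) %% 4L) + 1L
  }
  seq_int
}

# single-base indel events (Poisson in site x branch length)
.apply_indels <- function(seq_int, d, rate) {
  if (rate <= 0 || d <= 0) return(seq_int)
  n_events <- rpois(1, rate * d * length(seq_int))
  for (k in seq_len(n_events)) {
    if (runif(1) < 0.5 && length(seq_int) > 1L) {
      seq_int <- seq_int[-sample.int(length(seq_int), 1L)]
    } else {
      pos <- sample.int(length(seq_int) + 1L, 1L)
      seq_int <- append(seq_int, sample.int(4L, 1L), after = pos - 1L)
    }
  }
  seq_int
}

.BASES <- c("A", "C", "G", "T")

#' Simulate marker sequences over a taxonomy
#'
#' One uniform-random root sequence per marker evolves independently down the
#' rank-balanced tree (family, genus, species, specimen branches, each scaled
#' by the marker's rate multiplier).  Per-record missingness is applied last.
#' The random stream is consumed in documented order: sequences (markers in
#' configuration order, lineages in taxonomy order), then missingness.
#'
#' @param taxonomy data.frame from [simulate_taxonomy()].
#' @param cfg a [sim_config()].
#' @return List with `library` (a [ref_library()]) and `truth` (list with
#'   `taxonomy` and a `records` presence table of specimen x marker).
#' @export
simulate_sequences <- function(taxonomy, cfg) {
  stopifnot(inherits(cfg, "sim_config"), nrow(taxonomy) >= 1)
  set.seed(cfg$seed + 1L)
  dv <- cfg$divergence
  specs <- unique(taxonomy)
  rec_list <- list()
  for (prof in cfg$markers) {
    r <- prof$rate_multiplier
    root <- sample.int(4L, prof$base_length, replace = TRUE)
    for (fam in unique(specs$family)) {
      fseq <- .apply_indels(.jc_evolve(root, dv[["family"]] * r),
                            dv[["family"]] * r, prof$indel_rate)
      fam_rows <- specs[specs$family == fam, ]
      for (gen in unique(fam_rows$genus)) {
        gseq <- .apply_indels(.jc_evolve(fseq, dv[["genus"]] * r),
                              dv[["genus"]] * r, prof$indel_rate)
        gen_rows <- fam_rows[fam_rows$genus == gen, ]
        for (spp in unique(gen_rows$species)) {
          sseq <- .apply_indels(.jc_evolve(gseq, dv[["species"]] * r),
                                dv[["species"]] * r, prof$indel_rate)
          ids <- gen_rows$specimen_id[gen_rows$species == spp]
          for (id in ids) {
            q <- .apply_indels(.jc_evolve(sseq, dv[["intraspecific"]] * r),
                               dv[["intraspecific"]] * r, prof$indel_rate)
            rec_list[[length(rec_list) + 1L]] <- data.frame(
              specimen_id = id, marker_id = prof$marker_id,
              sequence = paste(.BASES[q], collapse = ""))
          }
        }
      }
    }
  }
  rec <- do.call(rbind, rec_list)
  # missingness, one draw per record in the order generated above
  miss_prob <- setNames(vapply(cfg$markers, function(p) p$missing_prob, numeric(1)),
                        vapply(cfg$markers, function(p) p$marker_id, character(1)))
  drop <- runif(nrow(rec)) < miss_prob[rec$marker_id]
  rec <- rec[!drop, , drop = FALSE]
  idx <- match(rec$specimen_id, taxonomy$specimen_id)
  rec <- cbind(rec, taxonomy[idx, c("species", "genus", "family", "order")])
  lib <- ref_library(rec, markers = vapply(cfg$markers, function(p) p$marker_id,
                                           character(1)))
  presence <- data.frame(specimen_id = rec$specimen_id, marker_id = rec$marker_id)
  list(library = lib, truth = list(taxonomy = taxonomy, records = presence))
}

#' Simulate a complete reference library (taxonomy + sequences)
#'
#' @param cfg a [sim_config()].
#' @return As [simulate_sequences()].
#' @export
simulate_library <- function(cfg = sim_config()) {
  tax <- simulate_taxonomy(cfg)
  simulate_sequences(tax, cfg)
}

#' Simulate plot-structured bulk samples (post-denoising ASV table)
#'
#' Each plot receives a species subset drawn without replacement (among
#' library species carrying the amplicon marker); per-species read counts are
#' lognormal, rounded, minimum 1.  Each true ASV (the species' representative
#' marker sequence) spawns, with probability `error_asv_prob`, an erroneous
#' daughter differing by `error_substitutions` random substitutions, present
#' only in samples where the parent is present, with per-sample count
#' `round(parent * error_abundance_ratio)`.
#'
#' @param lib a [ref_library()].
#' @param cfg a [bulk_config()].
#' @return List with `table` (an [asv_table()]) and `truth` (list with
#'   `asvs`: asv_id, species, erroneous flag, parent asv; and `plots`: named
#'   list of true species per plot).
#' @export
simulate_bulk_samples <- function(lib, cfg = bulk_config()) {
  stopifnot(inherits(lib, "ref_library"), inherits(cfg, "bulk_config"))
  set.seed(cfg$seed)
  rec <- lib$records[lib$records$marker_id == cfg$marker_id, , drop = FALSE]
  all_sp <- sort(unique(lib$records$species))
  pool <- sort(unique(rec$species))
  lacking <- setdiff(all_sp, pool)
  if (length(lacking)) {
    warning("simulate_bulk_samples: ", length(lacking), " species lack marker ",
            cfg$marker_id, " and are skipped")
  }
  # representative sequence: record with the smallest specimen id
  rep_seq <- vapply(pool, function(s) {
    sub <- rec[rec$species == s, ]
    sub$sequence[order(sub$specimen_id)][1]
  }, character(1))

  plots <- sprintf("P%d", seq_len(cfg$n_plots))
  plot_species <- list()
  counts <- matrix(0L, nrow = length(pool), ncol = cfg$n_plots,
                   dimnames = list(pool, plots))
  for (p in seq_len(cfg$n_plots)) {
    k <- min(.draw_int(cfg$species_per_plot), length(pool))
    spp <- sort(pool[sample.int(length(pool), k)])
    plot_species[[plots[p]]] <- spp
    counts[spp, p] <- pmax(1L, as.integer(round(
      rlnorm(k, meanlog = log(200), sdlog = cfg$abundance_lognormal_sigma))))
  }
  used <- rowSums(counts) > 0
  counts <- counts[used, , drop = FALSE]
  species_used <- rownames(counts)

  asv_ids <- sprintf("ASV%03d", seq_along(species_used))
  seqs <- setNames(unname(rep_seq[species_used]), asv_ids)
  rownames(counts) <- asv_ids
  truth_asv <- data.frame(asv_id = asv_ids, species = species_used,
                          erroneous = FALSE, parent_asv = NA_character_)

  # erroneous daughters
  for (i in seq_along(asv_ids)) {
    if (runif(1) < cfg$error_asv_prob) {
      parent <- asv_ids[i]
      s <- strsplit(seqs[[parent]], "")[[1]]
      pos <- sample.int(length(s), cfg$error_substitutions)
      for (pp in pos) {
        s[pp] <- sample(setdiff(.BASES, s[pp]), 1L)
      }
      dcounts <- as.integer(round(counts[parent, ] * cfg$error_abundance_ratio))
      dcounts[counts[parent, ] == 0L] <- 0L
      if (sum(dcounts) == 0L) next  # daughter never observed; skip
      did <- sprintf("%s_err", parent)
      seqs[[did]] <- paste(s, collapse = "")
      counts <- rbind(counts, matrix(dcounts, nrow = 1,
                                     dimnames = list(did, colnames(counts))))
      truth_asv <- rbind(truth_asv,
                         data.frame(asv_id = did,
                                    species = truth_asv$species[i],
                                    erroneous = TRUE, parent_asv = parent))
    }
  }
  list(table = asv_table(seqs, counts),
       truth = list(asvs = truth_asv, plots = plot_species))
}

#' Plant identical-sequence species pairs into a library
#'
#' Validation utility for the decision rule: for each pair `(a, b)` of
#' species, every record of species `b` is overwritten, per marker, with
#' species `a`'s first sequence of that marker (and species `a`'s records are
#' likewise homogenised), so the two species become indistinguishable.  Under
#' a strict tie policy exactly the planted species become NIS.
#'
#' @param lib a [ref_library()].
#' @param pairs list of length-2 character vectors of species names.
#' @return The modified [ref_library()].
#' @export
plant_identical_species <- function(lib, pairs) {
  stopifnot(inherits(lib, "ref_library"))
  rec <- lib$records
  for (pr in pairs) {
    stopifnot(length(pr) == 2L, all(pr %in% rec$species))
    for (mk in lib$markers) {
      src <- rec$sequence[rec$species == pr[1] & rec$marker_id == mk]
      if (!length(src)) next
      sel <- rec$species %in% pr & rec$marker_id == mk
      rec$sequence[sel] <- src[1]
    }
  }
  ref_library(rec, markers = lib$markers)
}
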