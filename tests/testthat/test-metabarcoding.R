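# a handcrafted table: two real variants, one injected daughter of asv1
toy_table <- function() {
  s1 <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")  # 100 nt
  s2 <- chartr("AC", "TG", s1)                                # far from s1
  d1 <- mutate_seq_at(s1, c(3, 50))                           # 98% to s1
  counts <- rbind(asv1 = c(100L, 50L, 0L),
                  asv2 = c(30L, 0L, 200L),
                  asv3 = c(10L, 5L, 0L))  # daughter of asv1
  colnames(counts) <- c("P1", "P2", "P3")
  asv_table(c(asv1 = s1, asv2 = s2, asv3 = d1), counts)
}

mutate_seq_at <- function(s, pos) {
  v <- strsplit(s, "")[[1]]
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  paste(v, collapse = "")
}

test_that("asv_table validates its inputs", {
  counts <- matrix(1L, 1, 2, dimnames = list("a", c("s1", "s2")))
  expect_s3_class(asv_table(c(a = "ACGT"), counts), "asv_table")
  expect_error(asv_table(c(b = "ACGT"), counts), "one-to-one")
  bad <- counts; bad[1, 1] <- -1L
  expect_error(asv_table(c(a = "ACGT"), bad), "nonnegative")
})

test_that("assignment follows best identity with threshold and tie rules", {
  lib <- small_sim(seed = 41)$library
  rec <- lib$records[lib$records$marker_id == "ITS2", ]
  # an ASV equal to one reference sequence is assigned to that species at 100
  counts <- matrix(10L, 3, 1, dimnames = list(c("a1", "a2", "a3"), "P1"))
  far <- paste(sample(c("A", "C", "G", "T"), 450, TRUE), collapse = "")
  tab <- asv_table(c(a1 = rec$sequence[1], a2 = far,
                     a3 = rec$sequence[2]), counts)
  asg <- assign_asvs(tab, lib, assignment_config(marker = "ITS2"))
  expect_equal(asg$status[asg$asv_id == "a1"], "assigned")
  expect_equal(asg$species[asg$asv_id == "a1"], rec$species[1])
  expect_equal(asg$best_identity[asg$asv_id == "a1"], 100)
  # a random sequence cannot reach 95% identity at 70% coverage
  expect_equal(asg$status[asg$asv_id == "a2"], "below_threshold")

  # exact tie across two species -> ambiguous
  seq0 <- paste(rep("ACGT", 30), collapse = "")
  rec2 <- data.frame(specimen_id = c("u1", "v1"), marker_id = "mk",
                     sequence = seq0, species = c("U u", "V v"),
                     genus = c("U", "V"), family = "F", order = "O")
  lib2 <- ref_library(rec2)
  tab2 <- asv_table(c(q = seq0), matrix(5L, 1, 1, dimnames = list("q", "P1")))
  asg2 <- assign_asvs(tab2, lib2, assignment_config(marker = "mk"))
  expect_equal(asg2$status, "ambiguous")
  expect_true(is.na(asg2$species))

  expect_error(assign_asvs(tab2, lib2, assignment_config(marker = "none")),
               "no records")
})

test_that("reference sequences assign to their own species at identity 100", {
  lib <- small_sim(seed = 43)$library
  rec <- lib$records[lib$records$marker_id == "ITS2", ]
  rec <- rec[seq_len(min(25, nrow(rec))), ]
  counts <- matrix(1L, nrow(rec), 1,
                   dimnames = list(rec$specimen_id, "P1"))
  tab <- asv_table(setNames(rec$sequence, rec$specimen_id), counts)
  asg <- assign_asvs(tab, lib, assignment_config(marker = "ITS2"))
  ok <- asg$status == "assigned"
  expect_true(all(asg$best_identity == 100))
  expect_equal(asg$species[ok],
               rec$species[match(asg$asv_id[ok], rec$specimen_id)])
})

test_that("curation merges gated daughters and conserves per-sample reads", {
  tab <- toy_table()
  cur <- curate(tab)
  # asv3: identity 98 >= 84, co-occurrence 1, min ratio 10 >= 1 -> merged
  expect_equal(cur$merge_map$asv_id, "asv3")
  expect_equal(cur$merge_map$parent_id, "asv1")
  expect_setequal(rownames(cur$table$counts), c("asv1", "asv2"))
  expect_equal(colSums(cur$table$counts), colSums(tab$counts))
  expect_equal(unname(cur$table$counts["asv1", ]), c(110L, 55L, 0L))

  # similarity gate: a candidate below 84% identity is retained
  cur_hi <- curate(tab, curation_config(min_similarity = 99))
  expect_equal(nrow(cur_hi$merge_map), 0L)
  expect_equal(nrow(cur_hi$table$counts), 3L)

  # co-occurrence gate
  tab2 <- tab
  tab2$counts["asv3", 3] <- 7L  # daughter now present where parent absent
  tab2 <- asv_table(tab2$sequences, tab2$counts)
  cur2 <- curate(tab2, curation_config(min_cooccurrence = 0.95))
  expect_equal(nrow(cur2$merge_map), 0L)

  # abundance-ratio gate
  cur3 <- curate(tab, curation_config(min_ratio = 100))
  expect_equal(nrow(cur3$merge_map), 0L)
})

test_that("curation resolves merge chains to final survivors", {
  s1 <- paste(rep(c("A", "C", "G", "T"), 25), collapse = "")
  s2 <- mutate_seq_at(s1, 3)        # daughter of s1
  s3 <- mutate_seq_at(s1, c(3, 60)) # daughter of s2 (and of s1)
  counts <- rbind(a = c(1000L, 500L), b = c(100L, 50L), c = c(10L, 5L))
  colnames(counts) <- c("P1", "P2")
  tab <- asv_table(c(a = s1, b = s2, c = s3), counts)
  cur <- curate(tab)
  expect_equal(nrow(cur$table$counts), 1L)
  expect_equal(rownames(cur$table$counts), "a")
  expect_true(all(cur$merge_map$parent_id == "a"))  # chains resolved
  expect_equal(sum(cur$table$counts), sum(counts))
})

test_that("curation is monotone and reaches a fixed point", {
  sim <- small_sim(seed = 47)
  bulk <- suppressWarnings(simulate_bulk_samples(
    sim$library, bulk_config(error_asv_prob = 0.6, seed = 5)))
  tab <- bulk$table
  n_merged <- function(sim_th, co_th) {
    nrow(curate(tab, curation_config(min_similarity = sim_th,
                                     min_cooccurrence = co_th))$merge_map)
  }
  expect_gte(n_merged(84, 0.95), n_merged(95, 0.95))
  expect_gte(n_merged(84, 0.5), n_merged(84, 1.0))

  # fixed point: no daughter/parent pair in the output still passes all gates
  cur <- curate(tab)
  ct <- cur$table$counts
  tot <- rowSums(ct)
  ids <- rownames(ct)
  for (d in ids) {
    for (p in ids[tot > tot[d]]) {
      dm <- ct[d, ] > 0
      if (!sum(dm)) next
      co <- sum(ct[p, dm] > 0) / sum(dm)
      if (co < 0.95) next
      sh <- dm & ct[p, ] > 0
      if (min(ct[p, sh] / ct[d, sh]) < 1) next
      st <- pair_stats(cur$table$sequences[[d]], cur$table$sequences[[p]])
      if (st$n_denom < 0.9 * nchar(cur$table$sequences[[d]])) next
      expect_lt(st$identity, 84)
    }
  }
})

test_that("abundance report normalises within samples and tallies taxa", {
  lib <- tiny_library()
  counts <- rbind(x1 = c(40L, 10L), x2 = c(60L, 0L), x3 = c(0L, 7L))
  colnames(counts) <- c("P1", "P2")
  m1 <- lib$records[lib$records$marker_id == "m1", ]
  tab <- asv_table(c(x1 = m1$sequence[1], x2 = m1$sequence[3],
                     x3 = m1$sequence[4]), counts)
  asg <- assign_asvs(tab, lib, assignment_config(marker = "m1"))
  rep <- abundance_report(tab, asg, lib)
  ab <- rep$abundance
  for (s in unique(ab$sample)) {
    expect_equal(sum(ab$rel_abundance[ab$sample == s]), 1)
  }
  # single-species sample: relative abundance 1
  p2 <- ab[ab$sample == "P2", ]
  expect_equal(rep$tally$n_species, 3L)
  expect_equal(rep$tally$n_genera, 3L)
  expect_equal(rep$tally$n_families, 2L)

  # sample with zero assigned reads is flagged, not divided by zero
  counts0 <- cbind(counts, P3 = c(0L, 0L, 0L))
  tab0 <- asv_table(tab$sequences, counts0)
  rep0 <- abundance_report(tab0, asg, lib)
  expect_equal(rep0$empty_samples, "P3")
  expect_false("P3" %in% rep0$abundance$sample)
})

test_that("ASV tables round-trip through TSV + FASTA", {
  tab <- toy_table()
  d <- withr::local_tempdir()
  write_asv_table(tab, file.path(d, "c.tsv"), file.path(d, "s.fasta"))
  back <- read_asv_table(file.path(d, "c.tsv"), file.path(d, "s.fasta"))
  expect_equal(back$counts, tab$counts)
  expect_equal(back$sequences, tab$sequences)
})
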