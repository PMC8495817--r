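write_tree_tmp <- function(text) {
  f <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  writeLines(text, f)
  f
}

test_that("newick parsing keeps supports and rejects duplicates", {
  tr <- read_newick_with_support(write_tree_tmp("((a1,a2)95,(b1,b2)80);"))
  expect_equal(sort(tr$tip.label), c("a1", "a2", "b1", "b2"))
  expect_setequal(support_values(tr)[!is.na(support_values(tr))], c(95, 80))

  tr2 <- read_newick_with_support(write_tree_tmp("((a1,a2),(b1,b2));"))
  expect_true(all(is.na(support_values(tr2))))

  expect_error(read_newick_with_support(write_tree_tmp("((a1,a1),(b1,b2));")),
               "duplicate")
  expect_error(read_newick_with_support(write_tree_tmp("((a1,a2)150,b1);")),
               "outside")

  # round-trip preserves topology and supports
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick_with_support(tr, f)
  back <- read_newick_with_support(f)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_setequal(support_values(back), support_values(tr))
})

test_that("species monophyly reads bipartitions and applies the support threshold", {
  tr <- read_newick_with_support(write_tree_tmp("((a1,a2)95,(b1,b2)80);"))
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  res <- species_monophyly(tr, sp, phylo_config(min_support = 70))
  expect_true(all(res$is_monophyletic))
  expect_equal(res$support[res$species == "A"], 95)
  expect_equal(res$support[res$species == "B"], 80)
  expect_true(all(res$counted_as_MS))

  # interleaved tips: both species non-monophyletic
  tr2 <- read_newick_with_support(write_tree_tmp("((a1,b1)90,(a2,b2)85);"))
  res2 <- species_monophyly(tr2, sp)
  expect_false(any(res2$is_monophyletic))
  expect_false(any(res2$counted_as_MS))

  # supported clade below the threshold is monophyletic but not counted
  tr3 <- read_newick_with_support(
    write_tree_tmp("(((a1,a2)65,(b1,b2)90)99,(c1,c2)88);"))
  sp3 <- c(sp, c1 = "C", c2 = "C")
  res3 <- species_monophyly(tr3, sp3, phylo_config(min_support = 70))
  expect_true(res3$is_monophyletic[res3$species == "A"])
  expect_false(res3$counted_as_MS[res3$species == "A"])
  expect_true(res3$counted_as_MS[res3$species == "B"])

  # a leaf without a species mapping is fatal
  expect_error(species_monophyly(tr, sp[-1]), "without species mapping")
})

test_that("polytomy members without an exclusive edge are non-monophyletic", {
  tr <- read_newick_with_support(write_tree_tmp("(a1,a2,b1,(c1,c2)90);"))
  sp <- c(a1 = "A", a2 = "A", b1 = "B", c1 = "C", c2 = "C")
  res <- species_monophyly(tr, sp)
  expect_false(res$is_monophyletic[res$species == "A"])
  expect_true(res$is_monophyletic[res$species == "C"])
})

test_that("monophyly equals brute-force bipartition enumeration on random trees", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(5:32, 1)
    tr <- ape::rtree(n)
    tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
    # random species map: group tips into species of size 1-4
    sizes <- integer(0)
    while (sum(sizes) < n) sizes <- c(sizes, sample(1:4, 1))
    sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
    sp <- rep(sprintf("S%02d", seq_along(sizes)), sizes)[sample.int(n)]
    names(sp) <- tr$tip.label
    got <- species_monophyly(tr, sp, phylo_config(min_support = 70))
    want <- oracle_monophyly(tr, sp, min_support = 70)
    expect_equal(got$is_monophyletic, want$is_monophyletic)
    expect_equal(got$counted_as_MS, want$counted_as_MS)
    multi <- got$n_tips >= 2
    expect_equal(got$support[multi], want$support[multi])
  }
})

test_that("monophyly is invariant under re-rooting", {
  set.seed(5)
  tr <- ape::rtree(12)
  tr$node.label <- as.character(sample(50:100, tr$Nnode, replace = TRUE))
  sp <- setNames(rep(sprintf("S%d", 1:4), each = 3), tr$tip.label)
  base <- species_monophyly(tr, sp)
  for (out in sample(tr$tip.label, 3)) {
    rr <- ape::root(tr, outgroup = out, resolve.root = TRUE)
    rebased <- species_monophyly(rr, sp)
    expect_equal(rebased$is_monophyletic, base$is_monophyletic)
  }
})

test_that("raising min_support never increases MS", {
  set.seed(8)
  tr <- ape::rtree(20)
  tr$node.label <- as.character(sample(0:100, tr$Nnode, replace = TRUE))
  sp <- setNames(rep(sprintf("S%d", 1:5), each = 4), tr$tip.label)
  ms_at <- function(th) phylo_summary(
    species_monophyly(tr, sp, phylo_config(min_support = th)))$MS
  vals <- vapply(c(0, 30, 50, 70, 90, 100), ms_at, numeric(1))
  expect_true(all(diff(vals) <= 0))
})

test_that("neighbor joining recovers known topologies", {
  # three taxa: the unique unrooted topology
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- nj_tree(d3)
  expect_equal(ape::Ntip(tr3), 3L)

  # additive distances from the tree ((A:1,B:2):1,(C:3,D:1):1)
  dm <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 6
  dm["A", "D"] <- dm["D", "A"] <- 4
  dm["B", "C"] <- dm["C", "B"] <- 7
  dm["B", "D"] <- dm["D", "B"] <- 5
  dm["C", "D"] <- dm["D", "C"] <- 4
  # four-point condition for the split AB | CD
  expect_equal(dm["A", "B"] + dm["C", "D"], 7)
  expect_true(dm["A", "C"] + dm["B", "D"] == dm["A", "D"] + dm["B", "C"])
  expect_gt(dm["A", "C"] + dm["B", "D"], dm["A", "B"] + dm["C", "D"])
  tr4 <- nj_tree(dm)
  res <- species_monophyly(tr4, c(A = "AB", B = "AB", C = "CD", D = "CD"))
  expect_true(all(res$is_monophyletic))

  # input order does not change the unrooted topology
  perm <- c("C", "A", "D", "B")
  trp <- nj_tree(dm[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(trp))[1], 0)

  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
  bad <- dm; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
})

test_that("bootstrap supports are deterministic and reflect signal", {
  # clean two-block alignment: every column supports the same split
  block <- function(ch1, ch2, n1, n2, L) {
    rbind(matrix(ch1, n1, L), matrix(ch2, n2, L))
  }
  aln <- cbind(block("A", "T", 3, 3, 30), block("C", "G", 3, 3, 30))
  # add tip-distinguishing noise so distances are not all equal
  set.seed(2)
  for (i in 1:6) aln[i, sample(60, 2)] <- "N"
  rownames(aln) <- sprintf("t%d", 1:6)
  cfg <- phylo_config(n_bootstrap = 50, seed = 10)
  tr <- bootstrap_supports(aln, cfg = cfg)
  sup <- support_values(tr)
  res <- species_monophyly(tr, setNames(rep(c("X", "Y"), each = 3),
                                        rownames(aln)))
  expect_equal(res$support[res$species == "X"], 100)
  expect_equal(res$support[res$species == "Y"], 100)

  tr2 <- bootstrap_supports(aln, cfg = cfg)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))  # same seed

  # noise alignment without phylogenetic structure: supports not saturated
  set.seed(3)
  noise <- matrix(sample(c("A", "C", "G", "T"), 8 * 40, TRUE), 8, 40,
                  dimnames = list(sprintf("n%d", 1:8), NULL))
  trn <- bootstrap_supports(noise, cfg = phylo_config(n_bootstrap = 60, seed = 4))
  expect_true(any(support_values(trn) < 100, na.rm = TRUE))

  expect_error(bootstrap_supports(aln, cfg = phylo_config(n_bootstrap = 0)),
               "positive")
  expect_error(bootstrap_supports(aln[1:2, ]), "at least 3")
})

test_that("phylo_summary partitions species into SSA / SMA = MS + NMS", {
  res <- data.frame(species = c("a", "b", "c", "d"),
                    n_tips = c(1L, 2L, 3L, 2L),
                    is_monophyletic = c(NA, TRUE, TRUE, FALSE),
                    support = c(NA, 90, 60, NA),
                    counted_as_MS = c(FALSE, TRUE, FALSE, FALSE))
  s <- phylo_summary(res)
  expect_equal(s, list(SSA = 1L, SMA = 3L, MS = 1L, NMS = 2L))
  expect_equal(s$MS + s$NMS, s$SMA)

  none <- res[1, , drop = FALSE]
  expect_equal(phylo_summary(none)[c("SMA", "MS", "NMS")],
               list(SMA = 0L, MS = 0L, NMS = 0L))
})

test_that("end-to-end: well-separated synthetic species are supported monophyla", {
  cfg <- sim_config(n_families = 3L, genera_per_family = 2L,
                    species_per_genus = 2L, singleton_fraction = 0,
                    specimens_per_species_range = 3L,
                    markers = list(marker_profile("m1", 300, 1, 0, 0)),
                    seed = 6)
  sim <- simulate_library(cfg)
  rec <- sim$library$records
  tr <- bootstrap_supports(setNames(rec$sequence, rec$specimen_id),
                           cfg = phylo_config(n_bootstrap = 60, seed = 1))
  mono <- species_monophyly(tr, species_map(sim$library))
  s <- phylo_summary(mono)
  expect_equal(s$SMA, 12L)
  expect_equal(s$MS, s$SMA)  # every species recovered with strong support
})
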