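# Small handcrafted fixtures, built in code.

# three species, two markers, one species lacking the second marker
tiny_records <- function() {
  data.frame(
    specimen_id = c("sp1a", "sp1b", "sp2a", "sp3a", "sp1a", "sp2a"),
    marker_id = c("m1", "m1", "m1", "m1", "m2", "m2"),
    sequence = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGGAC", "TTGTACGTCC",
                 "GGGTACGTAC", "GGGTACGTTT"),
    species = c("A one", "A one", "B two", "C three", "A one", "B two"),
    genus = c("A", "A", "B", "C", "A", "B"),
    family = c("F1", "F1", "F1", "F2", "F1", "F1"),
    order = c("O1", "O1", "O1", "O1", "O1", "O1")
  )
}

tiny_library <- function() ref_library(tiny_records(), markers = c("m1", "m2"))

# write a library to a temp dir and return the read_library() argument list
write_tiny_files <- function(lib = tiny_library()) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  write_library(lib, d)
  list(sequence_files = setNames(file.path(d, paste0(lib$markers, ".fasta")),
                                 lib$markers),
       taxonomy_file = file.path(d, "taxonomy.tsv"),
       dir = d)
}

# mutate a sequence at k distinct interior-ish positions
mutate_seq <- function(s, k) {
  v <- strsplit(s, "")[[1]]
  pos <- sample(seq_along(v), k)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# a small fast-resolving simulated library used across tests
small_sim <- function(seed = 11) {
  simulate_library(sim_config(n_families = 4L, seed = seed))
}
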