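# Shared fixtures: canonical partitions over letters and the study-design
# parameter point (all internal branches 1.0, gamma = 0.3).

study_params <- function() network_params()

# Canonical partition of the first sum(sig) letters with clade sizes sig.
canonical_partition <- function(sig) {
  n <- sum(sig)
  tx <- LETTERS[seq_len(n)]
  i <- 1
  cl <- vector("list", 4)
  for (c in 1:4) {
    cl[[c]] <- tx[i:(i + sig[c] - 1)]
    i <- i + sig[c]
  }
  clade_partition(cl[[1]], cl[[2]], cl[[3]], cl[[4]])
}

ref_partition8 <- function() canonical_partition(c(2, 2, 2, 2))

# Independent brute-force count of ordered partitions of n taxa into four
# nonempty clades with sizes in {1, 2}: enumerate all 4^n assignments.
brute_force_candidate_count <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(0:3), n)))
  sum(apply(grid, 1, function(g) {
    sizes <- tabulate(g + 1L, 4L)
    all(sizes >= 1) && all(sizes <= 2)
  }))
}

# Quartet CFs on an unrooted 4-taxon species TREE with internal branch T:
# the textbook closed form, used as an independent oracle for tree-like
# (gamma = 0 or 1) limits.
tree_quartet_cfs <- function(T) {
  c(1 - 2 / 3 * exp(-T), exp(-T) / 3, exp(-T) / 3)
}
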