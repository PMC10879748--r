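# Synthetic data generators: exact tables, Gaussian perturbation,
# multinomial sampling, full gene-tree simulation.

test_that("true_cf_table is complete, consistent and exact", {
  p <- ref_partition8()
  tbl <- true_cf_table(p, study_params())
  expect_identical(nrow(tbl), 70L)   # choose(8, 4)
  expect_equal(tbl$CF12_34 + tbl$CF13_24 + tbl$CF14_23, rep(1, 70),
               tolerance = 1e-12)
  # the (E,F,G,H) row is the cherry-vs-cherry class at total path 3
  r <- which(tbl$taxon1 == "E" & tbl$taxon2 == "F" & tbl$taxon3 == "G")
  expect_equal(tbl$CF12_34[r], 1 - 2 / 3 * exp(-3), tolerance = 1e-12)
  expect_equal(tbl$CF13_24[r], exp(-3) / 3, tolerance = 1e-12)
})

test_that("true_cf_table supports clades of three taxa (tree-like rows filled)", {
  p9 <- clade_partition(c("A", "B"), c("C", "D"), c("E", "F"),
                        c("G", "H", "I"))
  tbl <- true_cf_table(p9, study_params())
  expect_identical(nrow(tbl), 126L)  # choose(9, 4)
  expect_equal(tbl$CF12_34 + tbl$CF13_24 + tbl$CF14_23, rep(1, 126),
               tolerance = 1e-12)
  # a quartet drawn entirely inside {G,H,I} plus one outsider is tree-like:
  # ((G,H),I) with unit internal branch, far outsider: major >= 1 - 2/3 e^-1
  r <- which(tbl$taxon1 == "A" & tbl$taxon2 == "G" & tbl$taxon3 == "H" &
               tbl$taxon4 == "I")
  # canonical columns for (A,G,H,I): split GH|AI is CF14_23's pairing of
  # taxon2=G with taxon3=H
  expect_gt(tbl$CF14_23[r], 0.7)
})

test_that("Gaussian perturbation has the right magnitude and determinism", {
  p <- ref_partition8()
  tbl <- true_cf_table(p, study_params())
  expect_identical(as.data.frame(perturb_gaussian(tbl, 0)),
                   as.data.frame(tbl))  # sigma = 0 is the identity
  s1 <- perturb_gaussian(tbl, 5e-4, seed = 7)
  s2 <- perturb_gaussian(tbl, 5e-4, seed = 7)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  dev <- as.matrix(s1[c("CF12_34", "CF13_24", "CF14_23")]) -
    as.matrix(tbl[c("CF12_34", "CF13_24", "CF14_23")])
  expect_lt(abs(sd(dev) - 5e-4) / 5e-4, 0.15)   # 210 draws
  expect_true(all(s1$CF12_34 >= 0 & s1$CF12_34 <= 1))
  # optional renormalization restores unit triples
  rn <- perturb_gaussian(tbl, 5e-3, seed = 7, renormalize = TRUE)
  expect_equal(rn$CF12_34 + rn$CF13_24 + rn$CF14_23, rep(1, 70),
               tolerance = 1e-12)
})

test_that("multinomial quartet sampling is reproducible and converges", {
  p <- canonical_partition(c(2, 1, 1, 2))
  k1 <- sample_gene_tree_quartets(p, study_params(), k = 1, seed = 5)
  M <- as.matrix(k1[c("CF12_34", "CF13_24", "CF14_23")])
  expect_true(all(apply(M, 1, function(r) setequal(r, c(0, 0, 1)) ||
                          all(sort(r) == c(0, 0, 1)))))
  a <- sample_gene_tree_quartets(p, study_params(), k = 500, seed = 9)
  b <- sample_gene_tree_quartets(p, study_params(), k = 500, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  big <- sample_gene_tree_quartets(p, study_params(), k = 1e6, seed = 11)
  tru <- true_cf_table(p, study_params())
  dev <- max(abs(as.matrix(big[c("CF12_34", "CF13_24", "CF14_23")]) -
                   as.matrix(tru[c("CF12_34", "CF13_24", "CF14_23")])))
  expect_lt(dev, 0.005)   # law of large numbers at k = 1e6
})

test_that("simulated gene trees parse, cover the leaf set, and are seeded", {
  p <- ref_partition8()
  gt <- simulate_gene_trees(p, study_params(), k = 20, seed = 3)
  expect_length(gt, 20L)
  trees <- ape::read.tree(text = paste(gt, collapse = "\n"))
  for (tr in trees) expect_setequal(tr$tip.label, LETTERS[1:8])
  expect_identical(simulate_gene_trees(p, study_params(), k = 20, seed = 3),
                   gt)
  expect_false(identical(simulate_gene_trees(p, study_params(), k = 20,
                                             seed = 4), gt))
})

test_that("gene-tree simulation reproduces the model CFs within sampling error", {
  p <- canonical_partition(c(2, 2, 1, 1))
  k <- 3000
  gt <- simulate_gene_trees(p, study_params(), k = k, seed = 21)
  cf <- cfs_from_gene_trees(gt, taxa = LETTERS[1:6])
  tru <- true_cf_table(p, study_params())
  M <- as.matrix(cf[c("CF12_34", "CF13_24", "CF14_23")])
  Tm <- as.matrix(tru[c("CF12_34", "CF13_24", "CF14_23")])
  se <- sqrt(pmax(Tm * (1 - Tm), 1e-12) / k)
  expect_true(all(abs(M - Tm) < 4 * se + 1e-9))
})

test_that("gamma = 0 gene trees always display the major-tree backbone", {
  # with no flow through h-v1, the hybrid clade joins through v2: the
  # quartet {A, C, E, F} (hybrid taxon, clade-1 taxon, clade-3 pair) must
  # never group A with C more often than chance allows... at gamma = 0 and
  # long t02/t23 the split A-with-E/F side dominates; check the exact CFs
  # are matched, which pins the backbone
  p <- canonical_partition(c(1, 1, 1, 2))
  pars <- network_params(gamma = 0, t02 = 3, t23 = 3)
  gt <- simulate_gene_trees(p, pars, k = 2000, seed = 13)
  cf <- cfs_from_gene_trees(gt, taxa = LETTERS[1:5])
  tru <- true_cf_table(p, pars)
  M <- as.matrix(cf[c("CF12_34", "CF13_24", "CF14_23")])
  Tm <- as.matrix(tru[c("CF12_34", "CF13_24", "CF14_23")])
  se <- sqrt(pmax(Tm * (1 - Tm), 1e-12) / 2000)
  expect_true(all(abs(M - Tm) < 4 * se + 1e-9))
})
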