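# Invariant sets: trivial structure, soundness, discrimination, symmetry,
# persistence.

test_that("trivial invariants count sums and exchangeable minors", {
  tr5 <- trivial_invariants(c(1, 1, 1, 2))
  expect_length(tr5, 7L)   # 4 sum-to-one + 3 minor equalities
  expect_identical(sum(attr(tr5, "kind") == "sum"), 4L)
  tr8 <- trivial_invariants(c(2, 2, 2, 2))
  expect_length(tr8, 19L + 18L)  # every class sums; all but (1,1,1,1) pair up
  # they vanish identically on model CFs
  a <- evaluate_cfs(c(1, 1, 1, 2), study_params())
  vals <- vapply(tr5, qp_eval, numeric(1),
                 x = matrix(a, 1, dimnames = list(NULL, names(a))))
  expect_true(all(abs(vals) < 1e-12))
})

test_that("derived invariants vanish on model concordance factors (soundness)", {
  set.seed(2024)
  draws <- random_params(60)
  for (sig in list(c(1, 1, 1, 2), c(2, 1, 1, 2), c(2, 2, 1, 2),
                   c(2, 2, 2, 2))) {
    inv <- invariant_sets(sig)
    expect_gt(length(inv$gens), 0)
    worst <- 0
    for (pp in draws)
      worst <- max(worst, max(abs(invariant_values(inv, evaluate_cfs(sig, pp)))))
    expect_lt(worst, 1e-10)
  }
})

test_that("generic off-model vectors receive a positive score", {
  inv <- invariant_sets(c(1, 1, 1, 2))
  a <- evaluate_cfs(c(1, 1, 1, 2), study_params())
  a_off <- a
  a_off[1] <- a_off[1] + 0.1
  expect_gt(invariant_score(a_off, inv), 1e-6)
  expect_lt(invariant_score(a, inv), 1e-10)
})

test_that("wrong partitions score positive for nearly all random draws (discrimination)", {
  sig <- c(2, 1, 1, 2)
  p <- canonical_partition(sig)
  taxa <- sort(unlist(p))
  cands <- enumerate_partitions(taxa)
  texts <- vapply(cands, format_partition, character(1))
  ok_texts <- c(format_partition(p), format_partition(symmetric_partner(p)))
  set.seed(31)
  n_pos <- 0L; n_tot <- 0L
  for (pp in random_params(5)) {
    tbl <- true_cf_table(p, pp)
    r <- rank_partitions(tbl, m = 5)
    wrong <- r$score[!(r$partition %in% ok_texts)]
    n_pos <- n_pos + sum(wrong > 1e-6)
    n_tot <- n_tot + length(wrong)
  }
  expect_gt(n_pos / n_tot, 0.95)
})

test_that("a signature and its n1/n2 swap carry mirrored invariant sets", {
  inv_a <- invariant_sets(c(2, 2, 1, 2))
  inv_b <- invariant_sets(c(2, 1, 2, 2))
  expect_identical(length(inv_a$gens), length(inv_b$gens))
  # scores agree through the induced relabeling: evaluate both on the same
  # underlying data via a partition and its symmetric partner
  p <- canonical_partition(c(2, 2, 1, 2))
  tbl <- perturb_gaussian(true_cf_table(p, study_params()), 1e-3, seed = 8)
  s1 <- invariant_score(map_to_a_vector(tbl, p), inv_a)
  s2 <- invariant_score(map_to_a_vector(tbl, symmetric_partner(p)), inv_b)
  expect_lt(abs(s1 - s2), 1e-12)
})

test_that("self-symmetric signatures give equal scores to symmetric partners on noisy data", {
  p <- ref_partition8()
  tbl <- perturb_gaussian(true_cf_table(p, study_params()), 5e-4, seed = 3)
  inv <- invariant_sets(c(2, 2, 2, 2))
  cands <- enumerate_partitions(LETTERS[1:8])
  set.seed(5)
  for (q in cands[sample(length(cands), 12)]) {
    s1 <- invariant_score(map_to_a_vector(tbl, q), inv)
    s2 <- invariant_score(map_to_a_vector(tbl, symmetric_partner(q)), inv)
    expect_lt(abs(s1 - s2), 1e-12)
  }
})

test_that("the five-taxon generators have degree two, like the published basis", {
  inv <- invariant_sets(c(1, 1, 1, 2))
  degs <- vapply(inv$gens, function(g) max(rowSums(g$expo)), numeric(1))
  expect_true(all(degs <= 2))
  expect_gte(length(inv$gens), 3L)
})

test_that("the interpolation route agrees with the exact route where both apply", {
  inv_e <- derive_invariants(c(1, 1, 1, 2), method = "elimination",
                             max_degree = 2)
  inv_i <- derive_invariants(c(1, 1, 1, 2), method = "interpolation",
                             max_degree = 2)
  canon <- function(inv) sort(vapply(inv$gens, function(g) {
    ord <- order(apply(g$expo, 1, paste, collapse = ","))
    paste(c(t(g$expo[ord, , drop = FALSE])), g$num[ord], g$den[ord],
          collapse = ";")
  }, character(1)))
  expect_identical(canon(inv_e), canon(inv_i))
})

test_that("invariant sets survive a JSON round trip and detect tampering", {
  inv <- invariant_sets(c(1, 1, 1, 2))
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  store_invariants(inv, f)
  back <- load_invariants(f)
  expect_identical(back$signature, inv$signature)
  expect_identical(length(back$gens), length(inv$gens))
  a <- evaluate_cfs(c(1, 1, 1, 2), study_params())
  expect_equal(invariant_values(back, a), invariant_values(inv, a))
  # corrupt one coefficient: checksum must catch it
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  obj$gens$num[[1]][1] <- obj$gens$num[[1]][1] + 1
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  expect_error(load_invariants(f), "checksum")
})

test_that("invariant_score is the Euclidean norm of the evaluated invariants", {
  inv <- invariant_sets(c(1, 1, 1, 2))
  a <- evaluate_cfs(c(1, 1, 1, 2), study_params())
  a[1] <- a[1] + 0.05
  vals <- invariant_values(inv, a)
  expect_equal(invariant_score(a, inv), sqrt(sum(vals^2)))
  expect_equal(invariant_score(a, inv, normalized = TRUE),
               sqrt(sum(vals^2) / length(vals)))
  expect_error(invariant_score(c(0.3, 0.3, 0.4), inv), "length")
})

test_that("published five-taxon basis is resolved and vanishes on model data", {
  res <- resolve_printed_1112_indices(n_draws = 40)
  # unique up to the n1/n2 exchange: exactly one mirror pair passes
  expect_lte(res$n_passing, 2L)
  expect_gte(res$n_passing, 1L)
  expect_lt(res$max_residual, 1e-10)
  # original indices partition into the four classes with majors on slot 1
  expect_identical(res$map$slot[res$map$original %in% c(7L, 22L, 31L)],
                   rep(1L, 3))
  expect_identical(unique(res$map$class[res$map$original %in% 28:30]), "1111")
  pv <- printed_basis_vanishing(n_draws = 40)
  expect_identical(pv$n_vanishing, pv$n_polys)
  expect_identical(pv$n_polys, 10L)
})
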