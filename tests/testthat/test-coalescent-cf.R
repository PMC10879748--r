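# The symbolic CF engine against closed forms, limits, and the
# Monte-Carlo coalescent oracle.

test_that("informative class counts match the combinatorics of each signature", {
  expect_identical(nrow(informative_classes(c(2, 2, 2, 2))), 19L)
  cl1112 <- informative_classes(c(1, 1, 1, 2))
  expect_identical(nrow(cl1112), 4L)
  expect_setequal(apply(cl1112, 1, paste, collapse = ""),
                  c("1111", "1102", "1012", "0112"))
  # four taxa, one per clade: only one drawable class
  expect_identical(nrow(informative_classes(c(1, 1, 1, 1))), 1L)
  # every class entry respects the clade size cap
  for (sig in list(c(2, 1, 1, 2), c(1, 2, 2, 1))) {
    cls <- informative_classes(sig)
    expect_true(all(t(cls) <= pmin(sig, 2)))
    expect_true(all(rowSums(cls) == 4))
  }
})

test_that("the (0,0,2,2) class reproduces the closed-form cherry formulas", {
  vars <- cf_param_vars()
  cfp <- cf_polynomials(c(0, 0, 2, 2))
  # major: 1 - (2/3) z2 z23 z3; minors: (1/3) z2 z23 z3
  e <- matrix(0L, 1, 9); e[1, match(c("z2", "z23", "z3"), vars)] <- 1L
  major <- qp_add(qp_const(1, 1, vars), qpoly(-2, 3, e, vars))
  minor <- qpoly(1, 3, e, vars)
  expect_true(qp_equal(cfp$slots[[1]], major))
  expect_true(qp_equal(cfp$slots[[2]], minor))
  expect_true(qp_equal(cfp$slots[[3]], minor))
  # numeric value at t = 1 everywhere
  a <- evaluate_cfs(c(2, 2, 2, 2), study_params())
  expect_equal(unname(a[1]), 1 - 2 / 3 * exp(-3), tolerance = 1e-12)
  expect_equal(unname(a[2]), exp(-3) / 3, tolerance = 1e-12)
})

test_that("the (1,1,1,1) class carries the hybrid mixture formula", {
  vars <- cf_param_vars()
  cfp <- cf_polynomials(c(1, 1, 1, 1))
  g <- qp_var("g", vars); one <- qp_const(1, 1, vars)
  z13 <- qp_var("z13", vars); z23 <- qp_var("z23", vars)
  # g (1 - (2/3) z13) + (1 - g) (1/3) z23
  expected <- qp_add(qp_mul(g, qp_sub(one, qp_scale(z13, 2, 3))),
                     qp_mul(qp_sub(one, g), qp_scale(z23, 1, 3)))
  expect_true(qp_equal(cfp$slots[[1]], expected))
  expect_false(cfp$minors_equal)   # generically distinct minors
})

test_that("every CF triple sums to one symbolically and minors are equal iff a clade contributes a pair", {
  one <- qp_const(1, 1, cf_param_vars())
  cls <- informative_classes(c(2, 2, 2, 2))
  for (i in seq_len(nrow(cls))) {
    cfp <- cf_polynomials(cls[i, ])
    expect_true(qp_equal(Reduce(qp_add, cfp$slots), one))
    expect_identical(cfp$minors_equal, any(cls[i, ] == 2L))
  }
})

test_that("classes not involving the hybrid clade are free of g, z0, z01, z02", {
  cls <- informative_classes(c(2, 2, 2, 2))
  off <- match(c("z0", "z01", "z02", "g"), cf_param_vars())
  for (i in which(cls[, 1] == 0L)) {
    cfp <- cf_polynomials(cls[i, ])
    for (s in 1:3) expect_true(all(cfp$slots[[s]]$expo[, off] == 0L))
  }
})

test_that("cf_system has the expected size and parameter support", {
  sys8 <- cf_system(c(2, 2, 2, 2))
  expect_length(sys8$polys, 57L)
  expect_length(cf_system_vars(sys8), 9L)
  sys5 <- cf_system(c(1, 1, 1, 2))
  expect_length(sys5$polys, 12L)
  expect_error(cf_system(c(3, 2, 2, 1)), "unsupported")
})

test_that("evaluated CFs are proper probabilities with unit triples", {
  set.seed(11)
  for (pp in random_params(5)) {
    a <- evaluate_cfs(c(2, 2, 2, 2), pp)
    expect_true(all(a > 0 & a < 1))
    expect_equal(colSums(matrix(a, 3)), rep(1, 19), tolerance = 1e-12)
  }
})

test_that("the star-tree limit sends every CF to 1/3", {
  eps <- network_params(1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9, 1e-9,
                        gamma = 0.3)
  a <- evaluate_cfs(c(2, 2, 2, 2), eps)
  expect_equal(unname(a), rep(1 / 3, 57), tolerance = 1e-6)
})

test_that("gamma = 1 reduces to the displayed tree obtained by deleting h-v2", {
  # with gamma = 1 every hybrid lineage follows h-v1: the displayed tree
  # is the caterpillar with clade 0 attached at h on the v1 side; internal
  # path lengths of each quartet follow by reading the tree
  pars <- network_params(t0 = 0.8, t1 = 1.2, t2 = 0.9, t3 = 1.1,
                         t01 = 0.6, t02 = 0.4, t13 = 0.7, t23 = 0.5,
                         gamma = 1)
  a <- evaluate_cfs(c(2, 2, 2, 2), pars)
  sys <- cf_system(c(2, 2, 2, 2))
  # class (1,1,1,1): internal edge separating {x0,x1} from {x2,x3} is t13
  i <- which(sys$a_index$class == "1111" & sys$a_index$slot == 1)
  expect_equal(unname(a[i]), tree_quartet_cfs(0.7)[1], tolerance = 1e-12)
  # class (2,0,0,2): clade-0 pair vs clade-3 pair, path t0 + t01 + t13 + t3
  i2 <- which(sys$a_index$class == "2002" & sys$a_index$slot == 1)
  expect_equal(unname(a[i2]), tree_quartet_cfs(0.8 + 0.6 + 0.7 + 1.1)[1],
               tolerance = 1e-12)
  # class (0,2,2,0): cherry pair paths t1 + t13 + t23 + t2 on the tree
  i3 <- which(sys$a_index$class == "0220" & sys$a_index$slot == 1)
  expect_equal(unname(a[i3]), tree_quartet_cfs(1.2 + 0.7 + 0.5 + 0.9)[1],
               tolerance = 1e-12)
})

test_that("Monte-Carlo coalescent simulation agrees with the symbolic CFs", {
  pars <- network_params(t0 = 1.3, t1 = 0.8, t2 = 1.1, t3 = 0.9,
                         t01 = 0.7, t02 = 1.2, t13 = 1.0, t23 = 0.6,
                         gamma = 0.35)
  sys <- cf_system(c(2, 2, 2, 2))
  a <- evaluate_cfs(c(2, 2, 2, 2), pars)
  nsim <- 2e4
  for (key in c("0022", "1111", "2002", "2110")) {
    cls <- as.integer(strsplit(key, "")[[1]])
    mc <- mc_quartet_cfs(cls, pars, nsim = nsim, seed = 91)
    truth <- a[sys$a_index$class == key]
    se <- sqrt(pmax(truth * (1 - truth), 1e-12) / nsim)
    expect_true(all(abs(mc - truth) < 3.5 * se),
                info = paste("class", key, ":", paste(round(mc, 4),
                                                      collapse = ",")))
  }
})

test_that("Monte-Carlo edge cases behave as expected", {
  one_draw <- mc_quartet_cfs(c(0, 0, 2, 2), study_params(), nsim = 1, seed = 4)
  expect_equal(sort(unname(one_draw)), c(0, 0, 1))   # one-hot
  # gamma = 0 and gamma = 1 agree with the two displayed trees
  for (g in c(0, 1)) {
    pars <- network_params(gamma = g)
    mc <- mc_quartet_cfs(c(1, 1, 1, 1), pars, nsim = 2e4, seed = 5)
    truth <- evaluate_cfs(c(2, 2, 2, 2), pars)
    sys <- cf_system(c(2, 2, 2, 2))
    tr <- truth[sys$a_index$class == "1111"]
    se <- sqrt(pmax(tr * (1 - tr), 1e-12) / 2e4)
    expect_true(all(abs(mc - tr) < 3.5 * se + 1e-9))
  }
})

test_that("pendant-length independence: CFs ignore stems of singleton clades", {
  # t2 and t3 are pendant for signature (2,2,1,1) and must not matter
  a1 <- evaluate_cfs(c(2, 2, 1, 1), network_params(t2 = 0.1, t3 = 5))
  a2 <- evaluate_cfs(c(2, 2, 1, 1), network_params(t2 = 2.7, t3 = 0.2))
  expect_equal(a1, a2, tolerance = 1e-14)
})
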