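# Numeric concordance factors and coalescent simulation on a network built
# from an arbitrary clade partition.
#
# Clades of any size are attached to the cycle: a clade with m taxa is a
# ladder (caterpillar) tree with internal branches of length `inner`
# (default 1.0 coalescent unit) and a stem of length t_c to its cycle node.
# Only internal branch lengths affect concordance factors; pendant lengths
# are chosen to keep each clade subtree ultrametric and matter only for the
# branch lengths written on simulated gene trees.

# Edge layout and per-taxon lineage paths (leaf to root at v3, pendant
# included).  Clade-0 paths stop at the hybrid node h; the continuation
# through e01/e13 or e02/e23 depends on the per-lineage hybrid choice.
.network_structure <- function(p, params, inner = 1) {
  stopifnot(inherits(p, "clade_partition"), inherits(params, "network_params"))
  lens <- c(e01 = params$t01, e02 = params$t02,
            e13 = params$t13, e23 = params$t23)
  paths <- list()
  clade_of <- integer(0)
  edge_order <- character(0)
  for (cl in 0:3) {
    taxa <- p[[cl + 1]]
    m <- length(taxa)
    stem <- paste0("s", cl)
    lens[stem] <- params[[paste0("t", cl)]]
    inner_edges <- if (m > 2) paste0("i", cl, "_", 2:(m - 1)) else character(0)
    for (e in inner_edges) lens[e] <- inner
    for (j in seq_len(m)) {
      pend <- paste0("p", cl, "_", j)
      lens[pend] <- 1 + inner * (max(j, 2) - 2)   # ultrametric within the clade
      attach_at <- max(j, 2)
      mids <- if (m > 2 && attach_at <= m - 1)
        paste0("i", cl, "_", attach_at:(m - 1)) else character(0)
      paths[[taxa[j]]] <- c(pend, mids, stem)
      clade_of[taxa[j]] <- cl
    }
    edge_order <- c(edge_order, paste0("p", cl, "_", seq_len(m)),
                    inner_edges, stem)
  }
  edge_order <- c(edge_order, "e01", "e02", "e13", "e23")
  list(paths = paths, lens = lens, clade_of = clade_of,
       edge_order = edge_order, gamma = params$gamma)
}

# Continuation of a lineage path past its clade stem: clade 0 takes one of
# the hybrid routes, clades 1 and 2 descend a cycle edge, clade 3 sits at
# the root node v3.
.path_continuation <- function(clade, choice = NA) {
  switch(as.character(clade),
         "0" = if (choice == 1) c("e01", "e13") else c("e02", "e23"),
         "1" = "e13",
         "2" = "e23",
         "3" = character(0))
}

# Exact quartet CFs on the network for four taxa, by first-coalescence
# propagation (see cf_polynomials() for the argument); numeric version that
# supports clades of any size.  Returns c(CF12_34, CF13_24, CF14_23) for
# the quartet in the order given.
.quartet_cfs_exact <- function(struct, quartet) {
  g <- struct$gamma
  hyb <- which(struct$clade_of[quartet] == 0)
  choices <- if (length(hyb) == 0) list(integer(0)) else {
    grid <- do.call(expand.grid, rep(list(1:2), length(hyb)))
    lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  }
  tally <- numeric(3)
  pairs4 <- utils::combn(4, 2)
  for (choice in choices) {
    w <- prod(ifelse(choice == 1, g, 1 - g))
    if (w == 0) next
    paths <- lapply(seq_along(quartet), function(i) {
      tx <- quartet[i]
      cl <- struct$clade_of[tx]
      ch <- if (cl == 0) choice[match(i, hyb)] else NA
      c(struct$paths[[tx]], .path_continuation(cl, ch))
    })
    alive <- w
    for (e in struct$edge_order) {
      members <- which(vapply(paths, function(p) e %in% p, logical(1)))
      m <- length(members)
      if (m < 2) next
      C <- m * (m - 1) / 2
      surv <- exp(-C * struct$lens[[e]])
      dec <- alive * (1 - surv) / C
      prs <- utils::combn(members, 2)
      for (q in seq_len(ncol(prs)))
        tally[.split_of_pair(prs[1, q], prs[2, q])] <-
          tally[.split_of_pair(prs[1, q], prs[2, q])] + dec
      alive <- alive * surv
    }
    tally <- tally + alive / 3
  }
  tally
}

#' Monte-Carlo concordance factors for a quartet class
#'
#' Independent validation oracle for the symbolic CF polynomials: simulates
#' `nsim` genes under the coalescent on the rooted reference network (root
#' at v3; each lineage reaching the hybrid node picks the h-v1 parent with
#' probability gamma; pairwise coalescence at rate 1 within every edge) and
#' returns empirical quartet-topology frequencies in the slot order of
#' [cf_polynomials()].
#'
#' @param cls integer 4-vector quartet class.
#' @param params a [network_params()] object.
#' @param nsim number of simulated genes.
#' @param seed integer seed (all randomness is derived from it).
#' @return Numeric triple `(slot1, slot2, slot3)` summing to 1.
#' @export
mc_quartet_cfs <- function(cls, params, nsim = 1e5, seed = 1) {
  cls <- as.integer(cls)
  stopifnot(length(cls) == 4, all(cls >= 0), all(cls <= 2), sum(cls) == 4,
            nsim >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  g <- params$gamma
  n0 <- cls[1]
  clade_of <- rep(0:3, times = cls)
  tlen <- c(s0 = params$t0, e01 = params$t01, e02 = params$t02,
            s1 = params$t1, s2 = params$t2, s3 = params$t3,
            e13 = params$t13, e23 = params$t23)
  base <- function(tx, choice) {
    cl <- clade_of[tx]
    if (cl == 0) c(if (n0 == 2) "s0", if (choice == 1) c("e01", "e13")
                   else c("e02", "e23"))
    else if (cl == 1) c(if (cls[2] == 2) "s1", "e13")
    else if (cl == 2) c(if (cls[3] == 2) "s2", "e23")
    else if (cls[4] == 2) "s3" else character(0)
  }
  counts <- numeric(3)
  hyb <- which(clade_of == 0)
  for (s in seq_len(nsim)) {
    choice <- if (n0 > 0) 2L - as.integer(stats::runif(n0) < g) else integer(0)
    paths <- lapply(1:4, function(tx)
      base(tx, if (clade_of[tx] == 0) choice[match(tx, hyb)] else NA))
    block <- 1:4                      # block id per taxon
    first_merge <- NULL
    for (e in names(tlen)) {
      members <- unique(block[vapply(1:4, function(tx) e %in% paths[[tx]],
                                     logical(1))])
      m <- length(members)
      rem <- tlen[[e]]
      while (m >= 2) {
        dt <- stats::rexp(1, m * (m - 1) / 2)
        if (dt > rem) break
        rem <- rem - dt
        pick <- sample(m, 2)
        pr <- members[pick]
        if (is.null(first_merge)) first_merge <- which(block %in% pr)
        block[block == pr[2]] <- pr[1]
        members <- setdiff(members, pr[2])
        m <- m - 1
      }
    }
    if (is.null(first_merge)) {       # root population: uniform first pair
      pr <- sample(unique(block), 2)
      first_merge <- which(block %in% pr)
    }
    counts[.split_of_pair(first_merge[1], first_merge[2])] <-
      counts[.split_of_pair(first_merge[1], first_merge[2])] + 1
  }
  freq <- counts / nsim
  cfp <- cf_polynomials(cls)
  pred <- cfp$pred_split
  rest <- setdiff(1:3, pred)
  out <- c(freq[pred], freq[rest[1]], freq[rest[2]])
  names(out) <- paste0("slot", 1:3)
  out
}

# Save/restore .Random.seed so oracle calls do not disturb the caller's RNG
# stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate gene trees under the coalescent on a network
#'
#' Full coalescent simulation on the rooted network defined by a clade
#' partition and its parameters: each gene draws independent hybrid-parent
#' choices (probability `gamma` for h-v1) for every lineage or ancestral
#' block reaching the hybrid node, and lineages coalesce pairwise at rate 1
#' within every edge.  Unlike [sample_gene_tree_quartets()], quartet
#' topologies within one gene are dependent, as in real multilocus data.
#'
#' @param p a `clade_partition`.
#' @param params a [network_params()] object.
#' @param k number of gene trees.
#' @param seed integer seed.
#' @param inner internal branch length (coalescent units) inside clades with
#'   three or more taxa.
#' @return Character vector of `k` Newick strings (branch lengths in
#'   coalescent units).
#' @export
simulate_gene_trees <- function(p, params, k, seed = 1, inner = 1) {
  stopifnot(k >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  struct <- .network_structure(p, params, inner)
  taxa <- names(struct$paths)
  vapply(seq_len(k), function(gene) sim_one_gene(struct, taxa, struct$gamma),
         character(1))
}

# One gene: returns a Newick string.  Each block carries the age (in
# coalescent units above the leaves) of its subtree root, so branch lengths
# at a merge are merge_age - child_root_age.
sim_one_gene <- function(struct, taxa, g) {
  blocks <- lapply(taxa, function(tx) list(
    path = c(struct$paths[[tx]], if (struct$clade_of[[tx]] != 0)
      .path_continuation(struct$clade_of[[tx]])),
    entry = 0,                   # age at the bottom of the current edge
    root_age = 0, newick = tx, clade0 = struct$clade_of[[tx]] == 0))
  for (e in struct$edge_order) {
    len <- struct$lens[[e]]
    ids <- which(vapply(blocks, function(b) length(b$path) > 0 &&
                          b$path[1] == e, logical(1)))
    elapsed <- 0
    while (length(ids) >= 2) {
      m <- length(ids)
      dt <- stats::rexp(1, m * (m - 1) / 2)
      if (elapsed + dt > len) break
      elapsed <- elapsed + dt
      pick <- sort(sample(m, 2))
      i <- ids[pick[1]]; j <- ids[pick[2]]
      age <- blocks[[i]]$entry + elapsed
      blocks[[i]]$newick <- sprintf("(%s:%.8f,%s:%.8f)",
                                    blocks[[i]]$newick, age - blocks[[i]]$root_age,
                                    blocks[[j]]$newick, age - blocks[[j]]$root_age)
      blocks[[i]]$root_age <- age
      blocks[[j]] <- NULL
      ids <- which(vapply(blocks, function(b) length(b$path) > 0 &&
                            b$path[1] == e, logical(1)))
    }
    # advance every block through this edge
    for (i in seq_along(blocks)) {
      b <- blocks[[i]]
      if (length(b$path) > 0 && b$path[1] == e) {
        b$path <- b$path[-1]
        b$entry <- b$entry + len
        # a clade-0 block leaving its stem chooses a hybrid parent
        if (b$clade0 && length(b$path) == 0) {
          b$path <- .path_continuation(0, if (stats::runif(1) < g) 1 else 2)
          b$clade0 <- FALSE
        }
        blocks[[i]] <- b
      }
    }
  }
  # root population above v3
  age <- max(vapply(blocks, function(b) b$entry, numeric(1)))
  while (length(blocks) >= 2) {
    m <- length(blocks)
    age <- age + stats::rexp(1, m * (m - 1) / 2)
    pick <- sort(sample(m, 2))
    i <- pick[1]; j <- pick[2]
    blocks[[i]]$newick <- sprintf("(%s:%.8f,%s:%.8f)",
                                  blocks[[i]]$newick, age - blocks[[i]]$root_age,
                                  blocks[[j]]$newick, age - blocks[[j]]$root_age)
    blocks[[i]]$root_age <- age
    blocks[[j]] <- NULL
  }
  paste0(blocks[[1]]$newick, ";")
}
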