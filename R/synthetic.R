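# Synthetic concordance-factor data: the study conditions.
#
# Defaults throughout follow the simulation design the package is
# validated against: every internal branch of the network 1.0 coalescent
# unit, inheritance probability gamma = 0.3, Gaussian noise standard
# deviations in {5e-4, 5e-5, 5e-6}, and gene-tree counts in
# {100, 1000, 10000}.

#' Exact concordance-factor table of a network
#'
#' One row per four-taxon subset of the partition's taxa, with the exact
#' model CFs computed by first-coalescence propagation on the network
#' (clades of any size; within-clade ladders use `inner` for their internal
#' branches).  On informative quartets the values coincide with
#' [evaluate_cfs()]; quartets drawing three or more taxa from one clade are
#' tree-like and are filled from the same engine, so the table is complete.
#'
#' @param p a `clade_partition` (clades of any size).
#' @param params a [network_params()] object.
#' @param inner internal branch length within clades of three or more taxa.
#' @return A canonical CF tibble with `choose(n, 4)` rows.
#' @examples
#' p <- clade_partition(c("A", "B"), c("C", "D"), c("E", "F"), c("G", "H"))
#' nrow(true_cf_table(p, network_params()))  # 70
#' @export
true_cf_table <- function(p, params = network_params(), inner = 1) {
  stopifnot(inherits(p, "clade_partition"))
  struct <- .network_structure(p, params, inner)
  taxa <- sort(unlist(p))
  subsets <- utils::combn(taxa, 4)
  cf <- t(apply(subsets, 2, function(q) .quartet_cfs_exact(struct, q)))
  out <- tibble::tibble(
    taxon1 = subsets[1, ], taxon2 = subsets[2, ],
    taxon3 = subsets[3, ], taxon4 = subsets[4, ],
    CF12_34 = cf[, 1], CF13_24 = cf[, 2], CF14_23 = cf[, 3])
  canonicalize_cf_table(out, tol = 1e-9)
}

#' Add Gaussian noise to a CF table
#'
#' Independent zero-mean Gaussian noise with standard deviation `sigma` is
#' added to every CF entry and values are clipped to `[0, 1]`.  Triples are
#' not renormalized by default (at the tiny sigmas of the study design the
#' perturbed triples remain essentially on the simplex); set
#' `renormalize = TRUE` to rescale each triple to sum to one.
#'
#' @param tbl a CF table.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @param renormalize rescale each triple to sum to 1.
#' @return A CF tibble of the same shape (sum-to-one checking disabled).
#' @export
perturb_gaussian <- function(tbl, sigma, seed = 1, renormalize = FALSE) {
  stopifnot(sigma >= 0)
  tbl <- canonicalize_cf_table(tbl, tol = NULL)
  if (sigma == 0) return(tbl)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  M <- as.matrix(tbl[.cf_cols])
  M <- M + matrix(stats::rnorm(length(M), 0, sigma), nrow(M), 3)
  M <- pmin(pmax(M, 0), 1)
  if (renormalize) M <- M / rowSums(M)
  tbl[.cf_cols] <- tibble::as_tibble(M)
  tbl
}

#' Multinomial gene-tree quartet sampling
#'
#' For each quartet, draws counts from Multinomial(`k`, true CF triple) and
#' converts them to frequencies — a fast stand-in for full gene-tree
#' simulation in which quartets are sampled independently of one another
#' (within-gene dependence between quartets is ignored; use
#' [simulate_gene_trees()] plus [cfs_from_gene_trees()] when it matters).
#'
#' @param p a `clade_partition`.
#' @param params a [network_params()] object.
#' @param k number of gene trees emulated per quartet.
#' @param seed integer seed.
#' @param inner internal branch length within clades of 3+ taxa.
#' @return A CF tibble with an `ngenes` column equal to `k`.
#' @export
sample_gene_tree_quartets <- function(p, params = network_params(), k = 1000,
                                      seed = 1, inner = 1) {
  stopifnot(k >= 1)
  tbl <- true_cf_table(p, params, inner)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  M <- as.matrix(tbl[.cf_cols])
  for (r in seq_len(nrow(M)))
    M[r, ] <- as.numeric(stats::rmultinom(1, k, M[r, ])) / k
  tbl[.cf_cols] <- tibble::as_tibble(M)
  tbl$ngenes <- k
  tbl
}
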