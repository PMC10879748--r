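# Concordance factors under the multispecies coalescent on the reference
# network.
#
# The reference network carries the four-node hybridization cycle
# h - v1 - v3 - v2 - h with clade i attached below cycle node v_i (clade 0
# below the hybrid node h).  Each clade contributes at most two sampled
# lineages; a two-lineage clade enters through its stem edge of length t_i,
# where the pair may already coalesce.  Branch lengths are in coalescent
# units and enter the formulas only through z_e = exp(-t_e); pendant edges
# never appear.  A lineage reaching h follows the hybrid edge h-v1 with
# inheritance probability g and h-v2 with probability 1-g.
#
# For four sampled lineages, the unrooted quartet topology is decided by the
# first coalescence event among them: the first pair to merge forms a cherry
# and fixes the split.  The engine therefore propagates, edge by edge toward
# the root (placed at v3), the exact probability that no coalescence has
# happened yet, splitting off decision mass on every edge that carries two
# or more lineages: with m lineages on an edge of length t, no pair merges
# with probability z^C (C = m(m-1)/2) and each particular pair is the first
# to merge with probability (1 - z^C)/C.  Above the root every pair is
# equally likely to merge first.  All of this is polynomial in the z_e and
# g, so the computation is carried out exactly over the rationals.

cf_param_vars <- function() c("z0", "z1", "z2", "z3", "z01", "z02", "z13", "z23", "g")

# Edge processing order (a topological order toward the root at v3) and the
# parameter variable attached to each edge.
.ref_edges <- c(s0 = "z0", e01 = "z01", e02 = "z02", s1 = "z1", s2 = "z2",
                s3 = "z3", e13 = "z13", e23 = "z23")

#' Network parameters
#'
#' Bundles the nine model parameters of the reference network: clade stem
#' lengths `t0..t3`, hybrid edge lengths `t01` (h-v1) and `t02` (h-v2),
#' cycle edge lengths `t13` (v1-v3) and `t23` (v2-v3) — all in coalescent
#' units — and the inheritance probability `gamma` (probability that a
#' lineage entering the hybrid node follows h-v1).  The defaults are the
#' simulation-study conditions: every internal branch 1.0 coalescent unit
#' and `gamma = 0.3`.
#'
#' @param t0,t1,t2,t3,t01,t02,t13,t23 nonnegative branch lengths.
#' @param gamma inheritance probability in `[0, 1]`.
#' @return A named list of class `network_params`.
#' @export
network_params <- function(t0 = 1, t1 = 1, t2 = 1, t3 = 1,
                           t01 = 1, t02 = 1, t13 = 1, t23 = 1, gamma = 0.3) {
  pars <- list(t0 = t0, t1 = t1, t2 = t2, t3 = t3,
               t01 = t01, t02 = t02, t13 = t13, t23 = t23, gamma = gamma)
  if (any(unlist(pars[1:8]) < 0)) stop("branch lengths must be nonnegative")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  structure(pars, class = "network_params")
}

#' Draw random network parameters
#'
#' Branch lengths are Uniform(0.05, 3) coalescent units and gamma is
#' Uniform(0.05, 0.95) — generic interior points of parameter space, used
#' when checking that invariants vanish on model-generated concordance
#' factors.
#'
#' @param n number of parameter sets.
#' @return A list of `network_params` objects.
#' @export
random_params <- function(n = 1) {
  lapply(seq_len(n), function(i) {
    t <- stats::runif(8, 0.05, 3)
    network_params(t[1], t[2], t[3], t[4], t[5], t[6], t[7], t[8],
                   gamma = stats::runif(1, 0.05, 0.95))
  })
}

# Numeric z/g vector (in cf_param_vars() order) from network_params.
params_to_z <- function(params) {
  stopifnot(inherits(params, "network_params"))
  c(z0 = exp(-params$t0), z1 = exp(-params$t1), z2 = exp(-params$t2),
    z3 = exp(-params$t3), z01 = exp(-params$t01), z02 = exp(-params$t02),
    z13 = exp(-params$t13), z23 = exp(-params$t23), g = params$gamma)
}

#' Informative four-taxon subset classes for a signature
#'
#' A four-taxon subset is informative about the hybridization cycle only
#' when at most two of its taxa come from any one clade; subsets drawing
#' three or more from a single clade involve the cycle through pendant
#' branches only.  Classes are four-vectors `(i, j, k, l)` counting taxa
#' drawn from clades `n0..n3`.
#'
#' @param sig an integer 4-vector of clade sizes (see
#'   [partition_signature()]).
#' @return Integer matrix with one row per class, lexicographically sorted.
#' @examples
#' nrow(informative_classes(c(2, 2, 2, 2)))  # 19
#' nrow(informative_classes(c(1, 1, 1, 2)))  # 4
#' @export
informative_classes <- function(sig) {
  sig <- partition_signature(sig)
  caps <- pmin(sig, 2L)
  grid <- as.matrix(expand.grid(l = 0:caps[4], k = 0:caps[3],
                                j = 0:caps[2], i = 0:caps[1]))
  grid <- grid[, 4:1, drop = FALSE]
  grid <- grid[rowSums(grid) == 4L, , drop = FALSE]
  grid <- grid[order(grid[, 1], grid[, 2], grid[, 3], grid[, 4]), , drop = FALSE]
  dimnames(grid) <- list(NULL, c("n0", "n1", "n2", "n3"))
  grid
}

# Split index of the pair {a, b} within taxa 1..4: 1 = 12|34, 2 = 13|24,
# 3 = 14|23 (the split that groups the pair together).
.split_of_pair <- function(a, b) {
  pr <- sort(c(a, b))
  partner <- if (pr[1] == 1L) pr[2] else setdiff(2:4, pr)
  partner - 1L
}

#' Symbolic concordance-factor polynomials for a quartet class
#'
#' Returns the three CF polynomials of a class on the reference network as
#' exact rational polynomials in `z0, z1, z2, z3, z01, z02, z13, z23, g`.
#' Slot 1 is the split predicted by the class (the split grouping same-clade
#' pairs, or — for class `(1,1,1,1)` — the split pairing the clade-0 taxon
#' with the clade-1 taxon); slots 2 and 3 are the remaining splits in
#' canonical order.  The three polynomials sum identically to 1.
#'
#' @param cls integer 4-vector, a row of [informative_classes()].
#' @return A list with elements `slots` (list of three `qpoly`), `class`,
#'   `pred_split`, and `minors_equal` (whether slots 2 and 3 are
#'   symbolically identical).
#' @examples
#' cf_polynomials(c(0, 0, 2, 2))$slots[[1]]  # 1 - (2/3) z2 z23 z3
#' @export
cf_polynomials <- function(cls) {
  cls <- as.integer(cls)
  if (length(cls) != 4 || any(cls < 0) || any(cls > 2) || sum(cls) != 4)
    stop("a quartet class has four entries in {0, 1, 2} summing to 4")
  key <- paste0("cf", paste(cls, collapse = ""))
  if (!is.null(.qi_cache[[key]])) return(.qi_cache[[key]])

  vars <- cf_param_vars()
  clade_of <- rep(0:3, times = cls)      # clade of taxa 1..4 (sorted by clade)
  n0 <- cls[1]

  # Lineage paths: edges traversed from entry point to the root at v3.
  base_path <- function(taxon, choice = NA) {
    cl <- clade_of[taxon]
    if (cl == 0) {
      p <- if (n0 == 2) "s0" else character(0)
      if (choice == 1) c(p, "e01", "e13") else c(p, "e02", "e23")
    } else if (cl == 1) {
      c(if (cls[2] == 2) "s1", "e13")
    } else if (cl == 2) {
      c(if (cls[3] == 2) "s2", "e23")
    } else {
      if (cls[4] == 2) "s3" else character(0)
    }
  }

  g <- qp_var("g", vars)
  one <- qp_const(1, 1, vars)
  one_minus_g <- qp_sub(one, g)

  hybrid_choices <- if (n0 == 0) list(integer(0)) else
    do.call(expand.grid, rep(list(1:2), n0))
  if (is.data.frame(hybrid_choices))
    hybrid_choices <- lapply(seq_len(nrow(hybrid_choices)),
                             function(i) as.integer(hybrid_choices[i, ]))

  tally <- list(qp_zero(vars), qp_zero(vars), qp_zero(vars))
  pairs4 <- utils::combn(4, 2)

  for (choice in hybrid_choices) {
    weight <- one
    for (c in choice)
      weight <- qp_mul(weight, if (c == 1) g else one_minus_g)
    hybrid_taxa <- which(clade_of == 0)
    paths <- lapply(1:4, function(tx) {
      ch <- if (clade_of[tx] == 0) choice[match(tx, hybrid_taxa)] else NA
      base_path(tx, ch)
    })
    alive <- weight
    for (e in names(.ref_edges)) {
      members <- which(vapply(paths, function(p) e %in% p, logical(1)))
      m <- length(members)
      if (m < 2) next
      C <- m * (m - 1) / 2
      zexp <- integer(length(vars))
      zexp[match(.ref_edges[[e]], vars)] <- C
      dec <- qp_scale(alive, 1, C)                 # alive * (1 - z^C)/C
      contrib <- qp_sub(dec, qp_mul_monomial(dec, zexp))
      prs <- utils::combn(members, 2)
      for (q in seq_len(ncol(prs))) {
        s <- .split_of_pair(prs[1, q], prs[2, q])
        tally[[s]] <- qp_add(tally[[s]], contrib)
      }
      alive <- qp_mul_monomial(alive, zexp)
    }
    # Root population above v3: all four lineages, every pair equally likely.
    for (q in seq_len(ncol(pairs4))) {
      s <- .split_of_pair(pairs4[1, q], pairs4[2, q])
      tally[[s]] <- qp_add(tally[[s]], qp_scale(alive, 1, 6))
    }
  }

  if (any(cls == 2)) {
    pair_clade <- which(cls == 2)[1] - 1L
    pair_taxa <- which(clade_of == pair_clade)
    pred <- .split_of_pair(pair_taxa[1], pair_taxa[2])
  } else {
    pred <- 1L                                  # (1,1,1,1): clade0-with-clade1
  }
  rest <- setdiff(1:3, pred)
  slots <- list(tally[[pred]], tally[[rest[1]]], tally[[rest[2]]])
  out <- list(slots = slots, class = cls, pred_split = pred,
              minors_equal = qp_equal(slots[[2]], slots[[3]]))
  .qi_cache[[key]] <- out
  out
}

#' The concordance-factor polynomial system of a signature
#'
#' Assembles the CF polynomials of every informative class of a signature
#' into one system: `3 * nrow(informative_classes(sig))` polynomials in the
#' branch-length exponentials and the inheritance probability, indexed by
#' the canonical a-ordering (classes lexicographic, three slots each).
#'
#' @param sig a supported signature (clade sizes in \{1, 2\}, 5-8 taxa).
#' @return A list of class `cf_system` with elements `signature`, `classes`,
#'   `polys` (list of `qpoly`, length `3 * nclasses`), and `a_index`
#'   (tibble mapping a-index to class and slot).
#' @examples
#' length(cf_system(c(1, 1, 1, 2))$polys)  # 12
#' @export
cf_system <- function(sig) {
  sig <- assert_supported_signature(partition_signature(sig))
  classes <- informative_classes(sig)
  polys <- vector("list", 3L * nrow(classes))
  idx <- tibble::tibble(a = seq_len(3L * nrow(classes)),
                        class = rep(apply(classes, 1, paste, collapse = ""),
                                    each = 3),
                        slot = rep(1:3, nrow(classes)))
  for (i in seq_len(nrow(classes))) {
    cfp <- cf_polynomials(classes[i, ])
    for (s in 1:3) polys[[3L * (i - 1L) + s]] <- cfp$slots[[s]]
  }
  structure(list(signature = sig, classes = classes, polys = polys,
                 a_index = idx),
            class = "cf_system")
}

#' @export
print.cf_system <- function(x, ...) {
  used <- cf_system_vars(x)
  cat("<cf_system> signature", sig_label(x$signature), "-",
      length(x$polys), "polynomials in", length(used), "parameter variables\n")
  invisible(x)
}

#' Parameter variables appearing in a CF system
#'
#' @param sys a `cf_system`.
#' @return Character vector of the parameter symbols that occur with nonzero
#'   exponent somewhere in the system.
#' @export
cf_system_vars <- function(sys) {
  stopifnot(inherits(sys, "cf_system"))
  used <- Reduce(`|`, lapply(sys$polys, function(p) colSums(p$expo) > 0))
  cf_param_vars()[used]
}

#' Evaluate the model concordance factors of a signature
#'
#' Plugs numeric parameters into the CF polynomial system, returning the
#' a-vector of true concordance factors in canonical order.
#'
#' @param sig a supported signature.
#' @param params a [network_params()] object.
#' @return Named numeric vector (`a1`, `a2`, ...); each consecutive triple
#'   sums to 1.
#' @examples
#' a <- evaluate_cfs(c(2, 2, 2, 2), network_params())
#' sum(a[1:3])
#' @export
evaluate_cfs <- function(sig, params) {
  sys <- cf_system(sig)
  z <- params_to_z(params)
  a <- vapply(sys$polys, qp_eval, numeric(1), x = z)
  names(a) <- paste0("a", seq_along(a))
  a
}
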