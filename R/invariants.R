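# Phylogenetic invariants: polynomials in the concordance-factor variables
# a_i that vanish whenever the a-vector arises from the model, for any
# branch lengths and inheritance probability.
#
# Every signature admits "trivial" invariants (each CF triple sums to one;
# the two minor CFs of a class whose minors are symbolically exchangeable
# are equal).  The nontrivial invariants are obtained by eliminating the
# nine network parameters from the CF polynomial map.  After substituting
# the trivial relations, each class contributes one free coordinate (its
# major CF) except the class (1,1,1,1), which contributes two; the
# elimination is carried out on these reduced coordinates, truncated at a
# fixed total degree (default 3; the known printed bases have degree <= 2).
#
# The elimination itself is exact linear algebra: the monomial-evaluation
# matrix of the reduced coordinates is built over a prime field at random
# parameter points, its reduced row-echelon form yields one canonical
# relation per non-pivot monomial (graded monomial order), coefficients are
# reconstructed as rationals from two primes by Chinese remaindering, only
# minimal generators (leading monomial not divisible by an earlier leading
# monomial) are kept, and every candidate is then verified symbolically by
# expanding the substituted polynomial in the parameter variables, working
# over two further prime coefficient fields.  Candidates that fail
# verification are dropped with a warning.

.derive_primes <- c(1048573, 1048583, 1048601)   # ~2^20; products stay exact
.verify_primes <- c(1048609, 1048613)

## ---- reduced coordinates ----

# One reduced coordinate per class (its major, slot 1) except class
# (1,1,1,1) which keeps slots 1 and 2.
reduced_vars <- function(sig) {
  sys <- cf_system(sig)
  idx <- sys$a_index
  keep <- idx$slot == 1L | (idx$class == "1111" & idx$slot == 2L)
  out <- idx[keep, ]
  out$var <- paste0("x", seq_len(nrow(out)))
  out
}

reduced_cf_polys <- function(sig) {
  sys <- cf_system(sig)
  rv <- reduced_vars(sig)
  sys$polys[rv$a]
}

## ---- monomials ----

# All monomials of total degree <= maxdeg in v variables, graded order
# (degree, then lexicographic on the exponent vector).  Row 1 is the
# constant monomial.
monomial_basis <- function(v, maxdeg) {
  rows <- list(matrix(0L, 1, v))
  for (d in seq_len(maxdeg)) {
    sel <- utils::combn(v + d - 1, d)               # stars and bars
    expo <- apply(sel, 2, function(s) tabulate(s - seq_len(d) + 1L, v))
    rows[[d + 1]] <- t(expo)
  }
  expo <- do.call(rbind, rows)
  key <- apply(expo, 1, function(e) paste(sprintf("%02d", e), collapse = ""))
  expo[order(rowSums(expo), key), , drop = FALSE]
}

monomial_values <- function(X, expo, p = NULL) {
  # X: points x v matrix of coordinate values; returns points x nmono.
  out <- matrix(if (is.null(p)) 1 else 1, nrow(X), nrow(expo))
  for (i in seq_len(nrow(expo))) {
    e <- expo[i, ]
    v <- rep(1, nrow(X))
    for (k in which(e > 0)) {
      v <- if (is.null(p)) v * X[, k]^e[k] else mod_mul(v, mod_pow(X[, k], e[k], p), p)
    }
    out[, i] <- v
  }
  out
}

## ---- modular linear algebra ----

# Reduced row echelon form mod p, processing columns left to right.
# Returns pivots (column indices) and the echelon matrix.  Dispatches to
# the compiled kernel; the R fallback is kept for reference and testing.
rref_mod <- function(V, p) {
  out <- .rref_mod_cpp(V, p)
  out$pivots <- as.integer(out$pivots)
  out
}

rref_mod_r <- function(V, p) {
  K <- nrow(V); n <- ncol(V)
  r <- 0L
  pivots <- integer(0)
  for (j in seq_len(n)) {
    if (r == K) break
    nz <- which(V[(r + 1):K, j] != 0)
    if (length(nz) == 0) next
    i0 <- r + nz[1]
    if (i0 != r + 1) V[c(r + 1L, i0), ] <- V[c(i0, r + 1L), ]
    V[r + 1L, ] <- mod_mul(V[r + 1L, ], mod_inv(V[r + 1L, j], p), p)
    f <- V[, j]
    f[r + 1L] <- 0
    nzr <- which(f != 0)
    if (length(nzr) > 0)
      V[nzr, ] <- (V[nzr, , drop = FALSE] -
                     outer(f[nzr], V[r + 1L, ])) %% p
    r <- r + 1L
    pivots <- c(pivots, j)
  }
  list(pivots = pivots, R = V[seq_len(r), , drop = FALSE])
}

# Rational reconstruction of c mod M with numerator/denominator bounded by
# floor(sqrt(M/2)); returns c(num, den) or NULL.
rational_reconstruct <- function(c, M) {
  B <- floor(sqrt(M / 2))
  r0 <- M; r1 <- c %% M
  s0 <- 0; s1 <- 1
  while (r1 >= B) {
    q <- r0 %/% r1
    tmp <- r0 - q * r1; r0 <- r1; r1 <- tmp
    tmp <- s0 - q * s1; s0 <- s1; s1 <- tmp
  }
  den <- abs(s1)
  if (den == 0 || den > B) return(NULL)
  num <- if (s1 < 0) -r1 else r1
  g <- .gcd(abs(num), den)
  c(num / g, den / g)
}

crt_pair <- function(c1, c2, p1, p2) {
  # value mod p1*p2 congruent to c1 mod p1 and c2 mod p2
  inv <- mod_inv(p1 %% p2, p2)
  t <- mod_mul(mod_red(c2 - c1, p2), inv, p2)
  c1 + p1 * t
}

## ---- symbolic verification over a prime coefficient field ----

# Sparse polynomial over F_q represented as a named numeric vector keyed by
# the exponent string of the parameter monomial.
.fq_from_qpoly <- function(poly, q) {
  if (length(poly$num) == 0) return(stats::setNames(numeric(0), character(0)))
  coef <- mod_mul(mod_red(poly$num, q), mod_inv(mod_red(poly$den, q), q), q)
  keys <- apply(poly$expo, 1, paste, collapse = ",")
  stats::setNames(coef, keys)
}

.fq_mul <- function(a, b, q) {
  if (length(a) == 0 || length(b) == 0) return(stats::setNames(numeric(0), character(0)))
  ea <- do.call(rbind, strsplit(names(a), ","))
  eb <- do.call(rbind, strsplit(names(b), ","))
  ea <- matrix(as.integer(ea), nrow(ea)); eb <- matrix(as.integer(eb), nrow(eb))
  i <- rep(seq_along(a), times = length(b))
  j <- rep(seq_along(b), each = length(a))
  coef <- mod_mul(a[i], b[j], q)
  expo <- ea[i, , drop = FALSE] + eb[j, , drop = FALSE]
  keys <- apply(expo, 1, paste, collapse = ",")
  agg <- rowsum(coef, keys) %% q
  out <- agg[, 1]
  out[out != 0]
}

.fq_axpy <- function(acc, s, poly, q) {
  # acc + s * poly (all mod q)
  if (length(poly) == 0 || s == 0) return(acc)
  add <- mod_mul(poly, s, q)
  common <- intersect(names(acc), names(add))
  new <- setdiff(names(add), names(acc))
  acc[common] <- (acc[common] + add[common]) %% q
  c(acc, add[new])
}

# Substituted polynomial of the reduced monomial `expo_row` over F_q, with
# memoized products.
.fq_subst_monomial <- function(expo_row, basis_fq, q, memo) {
  key <- paste(expo_row, collapse = ",")
  if (!is.null(memo[[key]])) return(memo[[key]])
  idx <- rep(seq_along(expo_row), times = expo_row)
  if (length(idx) == 0) {
    out <- stats::setNames(mod_red(1, q), paste(rep(0L, 9), collapse = ","))
  } else {
    out <- basis_fq[[idx[1]]]
    for (k in idx[-1]) out <- .fq_mul(out, basis_fq[[k]], q)
  }
  memo[[key]] <- out
  out
}

# Verify that sum_t coeff_t * prod(f_i^{e_ti}) is the zero polynomial,
# with coefficients reduced mod q (performed for each q in qs).
verify_relation_fq <- function(num, den, expo, polys, qs) {
  for (q in qs) {
    basis_fq <- lapply(polys, .fq_from_qpoly, q = q)
    memo <- new.env(parent = emptyenv())
    acc <- stats::setNames(numeric(0), character(0))
    for (t in seq_along(num)) {
      s <- mod_mul(mod_red(num[t], q), mod_inv(mod_red(den[t], q), q), q)
      sub <- .fq_subst_monomial(expo[t, ], basis_fq, q, memo)
      acc <- .fq_axpy(acc, s, sub, q)
    }
    if (any(acc != 0)) return(FALSE)
  }
  TRUE
}

## ---- trivial invariants ----

#' Trivial invariants of a signature
#'
#' For every informative class, the sum-to-one polynomial
#' `a1 + a2 + a3 - 1`; and, for every class whose two minor CF polynomials
#' are symbolically equal (every class drawing two taxa from some clade),
#' the minor-equality polynomial `a2 - a3`.
#'
#' @param sig a supported signature.
#' @return A list of `qpoly` polynomials over the a-variables of the
#'   signature, with a `kind` attribute (`"sum"` or `"minor"`).
#' @examples
#' length(trivial_invariants(c(1, 1, 1, 2)))  # 7
#' @export
trivial_invariants <- function(sig) {
  sys <- cf_system(sig)
  n_a <- length(sys$polys)
  avars <- paste0("a", seq_len(n_a))
  out <- list()
  kinds <- character(0)
  for (i in seq_len(nrow(sys$classes))) {
    base <- 3L * (i - 1L)
    e <- matrix(0L, 4, n_a)
    e[1, base + 1L] <- 1L; e[2, base + 2L] <- 1L; e[3, base + 3L] <- 1L
    out[[length(out) + 1L]] <- qpoly(c(1, 1, 1, -1), c(1, 1, 1, 1), e, avars)
    kinds <- c(kinds, "sum")
    cfp <- cf_polynomials(sys$classes[i, ])
    if (cfp$minors_equal) {
      e2 <- matrix(0L, 2, n_a)
      e2[1, base + 2L] <- 1L; e2[2, base + 3L] <- 1L
      out[[length(out) + 1L]] <- qpoly(c(1, -1), c(1, 1), e2, avars)
      kinds <- c(kinds, "minor")
    }
  }
  attr(out, "kind") <- kinds
  out
}

## ---- derivation ----

#' Derive the invariant set of a signature
#'
#' Computes a verified generating set of low-degree phylogenetic invariants
#' for a signature: the trivial invariants plus the minimal generators of
#' the degree-truncated elimination ideal of the reduced CF coordinates.
#'
#' Two routes are provided.  `"elimination"` (the default) performs the
#' parameter elimination by exact linear algebra over prime fields as
#' described above and is deterministic.  `"interpolation"` samples the
#' model numerically in double precision, reads the same canonical
#' relations off a rank-revealing QR factorization, and rationalizes
#' small-denominator coefficients.  Both routes verify every candidate
#' symbolically (full expansion of the substituted polynomial) and drop
#' failures, so the returned set is sound by construction; the set is also
#' closed under the n1/n2 clade exchange, which makes the invariant score
#' of a partition and of its symmetric partner agree to machine precision.
#'
#' When `max_degree` is `NULL` (the default) the truncation degree is
#' chosen automatically: derivation starts at degree 3 and the degree is
#' raised (up to 6, with a warning at the cap) until the resulting set
#' separates every same-signature reassignment of the clade roles, i.e.
#' model concordance factors read through a wrong assignment of the clades
#' to the cycle nodes receive a strictly positive score.  Signatures with
#' a two-taxon hybrid clade and two singleton clades need degree 5 for
#' this; most signatures are already separating at degree 3.
#'
#' @param sig a supported signature.
#' @param method `"elimination"` or `"interpolation"`.
#' @param max_degree truncation degree for the nontrivial invariants, or
#'   `NULL` (default) for automatic escalation.
#' @return An object of class `invariant_set`.
#' @export
derive_invariants <- function(sig, method = c("elimination", "interpolation"),
                              max_degree = NULL) {
  sig <- assert_supported_signature(partition_signature(sig))
  method <- match.arg(method)
  # derive in the canonical orientation (n1 >= n2) and map back, so that a
  # signature and its swap carry exactly mirrored sets
  key <- paste0("inv_", sig_label(sig), "_", method, "_",
                if (is.null(max_degree)) "auto" else max_degree)
  if (!is.null(.qi_cache[[key]])) return(.qi_cache[[key]])
  if (sig[2] < sig[3]) {
    canon <- derive_invariants(sig[c(1, 3, 2, 4)], method, max_degree)
    out <- .swap_invariant_set(canon)
    .qi_cache[[key]] <- out
    return(out)
  }
  if (is.null(max_degree)) {
    degree_cap <- 6L
    out <- NULL
    for (d in 3:degree_cap) {
      out <- derive_invariants(sig, method, max_degree = d)
      if (.separates_roles(out)) break
      if (d == degree_cap)
        warning("invariants for signature ", sig_label(sig), " do not ",
                "separate all clade-role reassignments at degree ", degree_cap)
    }
    .qi_cache[[key]] <- out
    return(out)
  }

  rv <- reduced_vars(sig)
  polys <- reduced_cf_polys(sig)
  v <- nrow(rv)
  expo <- monomial_basis(v, max_degree)
  nmono <- nrow(expo)
  K <- nmono + 100L

  if (method == "elimination") {
    cand <- .derive_modular(polys, expo, K)
  } else {
    cand <- .derive_numeric(polys, expo, K)
  }

  # symbolic verification of every candidate; drop failures
  keep <- logical(length(cand))
  for (i in seq_along(cand)) {
    keep[i] <- verify_relation_fq(cand[[i]]$num, cand[[i]]$den,
                                  cand[[i]]$expo, polys, .verify_primes)
  }
  if (any(!keep))
    warning(sum(!keep), " candidate invariant(s) failed symbolic verification",
            " and were dropped (signature ", sig_label(sig), ")")
  gens <- cand[keep]

  inv <- .new_invariant_set(sig, rv, gens,
                            provenance = if (method == "elimination")
                              "modular-elimination" else "numeric-interpolation")
  if (sig[2] == sig[3]) inv <- .symmetrize_invariant_set(inv)
  .qi_cache[[key]] <- inv
  inv
}

# Identifiability check driving the automatic degree escalation: model
# concordance factors for the signature, read through every wrong
# same-signature assignment of the clades to the four cycle roles, must
# score strictly positive (the true assignment and its n1/n2 swap being
# the only admissible zeros).  Uses fixed internal seeds, so the outcome
# is deterministic.
.separates_roles <- function(inv, n_draws = 3, tol = 1e-9) {
  sig <- inv$signature
  taxa <- LETTERS[seq_len(sum(sig))]
  cl <- vector("list", 4)
  i <- 1
  for (c in 1:4) { cl[[c]] <- taxa[i:(i + sig[c] - 1)]; i <- i + sig[c] }
  p <- clade_partition(cl[[1]], cl[[2]], cl[[3]], cl[[4]])
  perms <- list(c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3),
                c(1,4,3,2), c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1),
                c(2,4,1,3), c(2,4,3,1), c(3,1,2,4), c(3,1,4,2), c(3,2,1,4),
                c(3,2,4,1), c(3,4,1,2), c(3,4,2,1), c(4,1,2,3), c(4,1,3,2),
                c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1))
  wrong <- Filter(function(s) !identical(s, c(1L,2L,3L,4L)) &&
                    !identical(s, c(1L,3L,2L,4L)) &&
                    identical(sig[s], sig),
                  lapply(perms, as.integer))
  if (length(wrong) == 0) return(TRUE)
  draws <- withr_seed(81000 + sum(sig * c(1000, 100, 10, 1)), function()
    random_params(n_draws))
  for (pp in draws) {
    tbl <- true_cf_table(p, pp)
    for (s in wrong) {
      q <- clade_partition(cl[[s[1]]], cl[[s[2]]], cl[[s[3]]], cl[[s[4]]])
      if (invariant_score(map_to_a_vector(tbl, q), inv) <= tol) return(FALSE)
    }
  }
  TRUE
}

# Exact route: monomial-evaluation matrices over two ~2^20 prime fields at
# random parameter points, canonical RREF relations, CRT + rational
# reconstruction.
.derive_modular <- function(polys, expo, K) {
  nmono <- nrow(expo)
  res <- vector("list", 2)
  for (w in 1:2) {
    p <- .derive_primes[w]
    pts <- withr_seed(1000 + w, function()
      matrix(sample.int(p - 1L, K * 9L, replace = TRUE), K, 9))
    X <- vapply(polys, qp_eval_mod, numeric(K), x = pts, p = p)
    V <- monomial_values(X, expo, p)
    res[[w]] <- rref_mod(V, p)
  }
  if (!identical(res[[1]]$pivots, res[[2]]$pivots))
    stop("pivot structure disagrees between primes; rerun derivation")
  pivots <- res[[1]]$pivots
  nonpiv <- setdiff(seq_len(nmono), pivots)
  nonpiv <- .minimal_leading(nonpiv, expo)
  M <- .derive_primes[1] * .derive_primes[2]
  out <- list()
  for (j in nonpiv) {
    c1 <- res[[1]]$R[, j]; c2 <- res[[2]]$R[, j]
    nzi <- which(c1 != 0 | c2 != 0)
    num <- den <- numeric(length(nzi))
    ok <- TRUE
    for (t in seq_along(nzi)) {
      cc <- crt_pair(c1[nzi[t]], c2[nzi[t]], .derive_primes[1], .derive_primes[2])
      rr <- rational_reconstruct(cc, M)
      # re-check the congruence against both primes (operands stay < 2^53)
      if (is.null(rr) ||
          mod_red(rr[1] - c1[nzi[t]] * rr[2], .derive_primes[1]) != 0 ||
          mod_red(rr[1] - c2[nzi[t]] * rr[2], .derive_primes[2]) != 0) {
        ok <- FALSE; break
      }
      num[t] <- rr[1]; den[t] <- rr[2]
    }
    if (!ok) next
    # relation: mono_j - sum_t coeff_t * mono_{pivot_t}
    out[[length(out) + 1L]] <- list(
      num = c(1, -num), den = c(1, den),
      expo = rbind(expo[j, , drop = FALSE], expo[pivots[nzi], , drop = FALSE]))
  }
  out
}

# Floating-point route: least-squares relations from a rank-revealing QR,
# coefficients rationalized with denominators up to 1000.
.derive_numeric <- function(polys, expo, K) {
  nmono <- nrow(expo)
  K <- max(K, 5L * nmono)
  pts <- withr_seed(2000, function() matrix(stats::runif(K * 9L, 0.05, 0.95), K, 9))
  X <- vapply(polys, qp_eval, numeric(K), x = pts)
  V <- monomial_values(X, expo)
  # canonical graded pivots by incremental orthogonalization: a column is a
  # pivot when it is not (numerically) in the span of the earlier pivots
  Q <- matrix(0, K, 0)
  pivots <- integer(0)
  for (j in seq_len(nmono)) {
    col <- V[, j]
    res <- if (ncol(Q) > 0) col - Q %*% crossprod(Q, col) else col
    if (sqrt(sum(res^2)) > 1e-8 * max(1, sqrt(sum(col^2)))) {
      Q <- cbind(Q, res / sqrt(sum(res^2)))
      pivots <- c(pivots, j)
    }
  }
  nonpiv <- setdiff(seq_len(nmono), pivots)
  nonpiv <- .minimal_leading(nonpiv, expo)
  out <- list()
  for (j in nonpiv) {
    coef <- qr.coef(qr(V[, pivots, drop = FALSE]), V[, j])
    rat <- .rationalize(coef, max_den = 1000)
    if (is.null(rat)) next
    nz <- which(rat$num != 0)
    out[[length(out) + 1L]] <- list(
      num = c(1, -rat$num[nz]), den = c(1, rat$den[nz]),
      expo = rbind(expo[j, , drop = FALSE], expo[pivots[nz], , drop = FALSE]))
  }
  out
}

.rationalize <- function(x, max_den) {
  num <- den <- numeric(length(x))
  for (i in seq_along(x)) {
    best <- NULL
    for (d in seq_len(max_den)) {
      n <- round(x[i] * d)
      if (abs(n / d - x[i]) < 1e-6) { best <- c(n, d); break }
    }
    if (is.null(best)) return(NULL)
    g <- .gcd(abs(best[1]), best[2])
    num[i] <- best[1] / max(g, 1); den[i] <- best[2] / max(g, 1)
  }
  den[num == 0] <- 1
  list(num = num, den = den)
}

# Keep only relations whose leading monomial is not divisible by another
# (earlier or equal) leading monomial: the minimal generators of the
# truncated ideal under the graded order.
.minimal_leading <- function(nonpiv, expo) {
  if (length(nonpiv) <= 1) return(nonpiv)
  lead <- expo[nonpiv, , drop = FALSE]
  keep <- rep(TRUE, length(nonpiv))
  for (i in seq_along(nonpiv)) {
    for (j in seq_along(nonpiv)) {
      if (i == j || !keep[j]) next
      if (all(lead[j, ] <= lead[i, ]) && any(lead[j, ] < lead[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  nonpiv[keep]
}

withr_seed <- function(seed, fn) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fn()
}

## ---- invariant_set object ----

.new_invariant_set <- function(sig, rv, gens, provenance) {
  sys <- cf_system(sig)
  structure(list(
    signature = sig,
    a_index = sys$a_index,
    reduced = rv,
    trivial = trivial_invariants(sig),
    gens = gens,
    provenance = provenance), class = "invariant_set")
}

#' @export
print.invariant_set <- function(x, ...) {
  cat("<invariant_set> signature", sig_label(x$signature), "-",
      length(x$trivial), "trivial +", length(x$gens),
      "nontrivial invariants (", x$provenance, ")\n")
  invisible(x)
}

#' Number of invariants in a set
#'
#' @param inv an `invariant_set`.
#' @return Integer: trivial plus nontrivial invariant count.
#' @export
n_invariants <- function(inv) length(inv$trivial) + length(inv$gens)

# The n1<->n2 exchange permutation on the a-indices of a signature: class
# (i,j,k,l) maps to (i,k,j,l); slots of two-entry classes are fixed, slots
# 1 and 2 of class (1,1,1,1) swap.
.swap_a_permutation <- function(sig) {
  sys <- cf_system(sig)
  sig2 <- sig[c(1, 3, 2, 4)]
  sys2 <- cf_system(sig2)
  classes <- sys$a_index$class
  perm <- integer(nrow(sys$a_index))
  for (r in seq_len(nrow(sys$a_index))) {
    cls <- as.integer(strsplit(classes[r], "")[[1]])
    cls2 <- cls[c(1, 3, 2, 4)]
    slot <- sys$a_index$slot[r]
    slot2 <- if (all(cls == 1L)) c(2L, 1L, 3L)[slot] else slot
    perm[r] <- which(sys2$a_index$class == paste(cls2, collapse = "") &
                       sys2$a_index$slot == slot2)
  }
  perm                                  # a-index in sig maps to perm[] in sig2
}

# Map an invariant set for signature (n0,n1,n2,n3) to the set for the
# swapped signature (n0,n2,n1,n3) by relabeling reduced coordinates.
.swap_invariant_set <- function(inv) {
  sig <- inv$signature
  sig2 <- sig[c(1, 3, 2, 4)]
  perm <- .swap_a_permutation(sig)
  rv2 <- reduced_vars(sig2)
  # reduced var i of sig corresponds to a-index inv$reduced$a[i]; under the
  # swap it becomes a-index perm[...] of sig2, i.e. some reduced var of sig2
  var_map <- match(perm[inv$reduced$a], rv2$a)
  stopifnot(!anyNA(var_map))
  gens2 <- lapply(inv$gens, function(g) {
    e <- g$expo
    e2 <- e
    e2[, var_map] <- e
    list(num = g$num, den = g$den, expo = e2)
  })
  out <- .new_invariant_set(sig2, rv2, gens2, inv$provenance)
  out
}

# For self-symmetric signatures (n1 == n2), close the generator list under
# the exchange so that symmetric partners receive identical scores.
.symmetrize_invariant_set <- function(inv) {
  sig <- inv$signature
  perm <- .swap_a_permutation(sig)     # permutation of this signature's a's
  rv <- inv$reduced
  var_map <- match(perm[rv$a], rv$a)
  stopifnot(!anyNA(var_map))
  canon <- function(g) {
    ord <- order(apply(g$expo, 1, paste, collapse = ","))
    num <- g$num[ord]
    if (num[1] < 0) num <- -num          # sign does not affect the score
    paste(c(t(g$expo[ord, , drop = FALSE])), num, g$den[ord], collapse = ";")
  }
  # normalize each generator so its leading coefficient is 1 (they already
  # are) and compare term lists
  seen <- vapply(inv$gens, canon, character(1))
  extra <- list()
  for (g in inv$gens) {
    e2 <- g$expo
    e2[, var_map] <- g$expo
    g2 <- list(num = g$num, den = g$den, expo = e2)
    # re-sort so representation is canonical
    if (!(canon(g2) %in% c(seen, vapply(extra, canon, character(1)))))
      extra[[length(extra) + 1L]] <- g2
  }
  inv$gens <- c(inv$gens, extra)
  inv
}

## ---- evaluation ----

#' Evaluate all invariants of a set on an a-vector
#'
#' @param inv an `invariant_set`.
#' @param a numeric a-vector in the canonical order of the signature (as
#'   returned by [evaluate_cfs()] or [map_to_a_vector()]).
#' @return Numeric vector of invariant values (trivial first, then
#'   nontrivial generators).
#' @export
invariant_values <- function(inv, a) {
  if (length(a) != nrow(inv$a_index))
    stop("a-vector has length ", length(a), " but signature ",
         sig_label(inv$signature), " expects ", nrow(inv$a_index))
  tv <- vapply(inv$trivial, qp_eval, numeric(1),
               x = matrix(a, 1, dimnames = list(NULL, paste0("a", seq_along(a)))))
  x <- a[inv$reduced$a]
  gv <- vapply(inv$gens, function(g) {
    s <- 0
    for (t in seq_along(g$num)) {
      m <- g$num[t] / g$den[t]
      e <- g$expo[t, ]
      for (k in which(e > 0)) m <- m * x[k]^e[k]
      s <- s + m
    }
    s
  }, numeric(1))
  c(tv, gv)
}

#' Invariant score of an a-vector
#'
#' The L2 norm of the vector of evaluated invariants: zero exactly on the
#' model variety, and the ranking criterion for candidate networks.
#'
#' @inheritParams invariant_values
#' @param normalized divide by the square root of the number of invariants
#'   (optional; the raw norm is the default and is what the ranking uses).
#' @return A nonnegative number.
#' @export
invariant_score <- function(a, inv, normalized = FALSE) {
  vals <- invariant_values(inv, a)
  s <- sqrt(sum(vals^2))
  if (normalized) s / sqrt(length(vals)) else s
}

#' Nontrivial invariants as polynomials in the a-variables
#'
#' Expands the internal reduced-coordinate representation of the derived
#' generators into `qpoly` objects over the full a-alphabet of the
#' signature.
#'
#' @param inv an `invariant_set`.
#' @return A list of `qpoly` objects.
#' @export
invariant_polynomials <- function(inv) {
  n_a <- nrow(inv$a_index)
  avars <- paste0("a", seq_len(n_a))
  lapply(inv$gens, function(g) {
    e <- matrix(0L, nrow(g$expo), n_a)
    e[, inv$reduced$a] <- g$expo
    qpoly(g$num, g$den, e, avars)
  })
}
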