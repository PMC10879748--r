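# Sparse multivariate polynomials with exact rational coefficients.
#
# Coefficients are stored as numerator/denominator pairs held in doubles;
# every intermediate stays far below 2^53, so the arithmetic is exact.
# This tiny kernel is all the computer algebra the package needs: the
# concordance-factor polynomials, the trivial and derived invariants, and
# the parameter-elimination step are all built on it.

.gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(active <- b > 0)) {
    r <- a[active] %% b[active]
    a[active] <- b[active]
    b[active] <- r
  }
  pmax(a, 1)
}

#' Construct a sparse rational polynomial
#'
#' @param num integer numerators, one per term.
#' @param den positive integer denominators, one per term.
#' @param expo integer matrix of exponents, one row per term, one column per
#'   variable.
#' @param vars character vector naming the variables (columns of `expo`).
#' @return An object of class `qpoly`.
#' @keywords internal
qpoly <- function(num, den, expo, vars) {
  stopifnot(length(num) == length(den), nrow(expo) == length(num),
            ncol(expo) == length(vars), all(den > 0))
  p <- structure(list(num = as.numeric(num), den = as.numeric(den),
                      expo = expo, vars = vars), class = "qpoly")
  qp_normalize(p)
}

qp_zero <- function(vars) {
  structure(list(num = numeric(0), den = numeric(0),
                 expo = matrix(0L, 0, length(vars)), vars = vars),
            class = "qpoly")
}

qp_const <- function(num, den, vars) {
  if (num == 0) return(qp_zero(vars))
  qpoly(num, den, matrix(0L, 1, length(vars)), vars)
}

qp_var <- function(name, vars) {
  e <- matrix(0L, 1, length(vars))
  e[1, match(name, vars)] <- 1L
  qpoly(1, 1, e, vars)
}

# Combine duplicate monomials, reduce fractions, drop zeros, sort terms.
qp_normalize <- function(p) {
  if (length(p$num) == 0) return(p)
  key <- apply(p$expo, 1, paste, collapse = ",")
  if (anyDuplicated(key)) {
    groups <- split(seq_along(key), key)
    num <- den <- numeric(length(groups))
    expo <- matrix(0L, length(groups), ncol(p$expo))
    for (i in seq_along(groups)) {
      idx <- groups[[i]]
      n <- p$num[idx[1]]; d <- p$den[idx[1]]
      for (j in idx[-1]) {           # exact rational sum of the group
        n2 <- p$num[j]; d2 <- p$den[j]
        g <- .gcd(d, d2)
        n <- n * (d2 / g) + n2 * (d / g)
        d <- d * (d2 / g)
        g2 <- .gcd(n, d)
        n <- n / g2; d <- d / g2
      }
      num[i] <- n; den[i] <- d
      expo[i, ] <- p$expo[idx[1], ]
    }
    p$num <- num; p$den <- den; p$expo <- expo
  }
  g <- .gcd(p$num, p$den)
  p$num <- p$num / g; p$den <- p$den / g
  keep <- p$num != 0
  p$num <- p$num[keep]; p$den <- p$den[keep]
  p$expo <- p$expo[keep, , drop = FALSE]
  if (length(p$num) > 1) {
    ord <- order(apply(p$expo, 1, paste, collapse = ","))
    p$num <- p$num[ord]; p$den <- p$den[ord]
    p$expo <- p$expo[ord, , drop = FALSE]
  }
  stopifnot(max(abs(p$num), 0) < 2^52, max(p$den, 0) < 2^52)
  p
}

qp_add <- function(p, q) {
  stopifnot(identical(p$vars, q$vars))
  qp_normalize(structure(list(num = c(p$num, q$num), den = c(p$den, q$den),
                              expo = rbind(p$expo, q$expo), vars = p$vars),
                         class = "qpoly"))
}

qp_sub <- function(p, q) {
  q$num <- -q$num
  qp_add(p, q)
}

# Multiply by the rational scalar num/den.
qp_scale <- function(p, num, den = 1) {
  if (num == 0) return(qp_zero(p$vars))
  p$num <- p$num * num
  p$den <- p$den * den
  qp_normalize(p)
}

qp_mul <- function(p, q) {
  stopifnot(identical(p$vars, q$vars))
  np <- length(p$num); nq <- length(q$num)
  if (np == 0 || nq == 0) return(qp_zero(p$vars))
  i <- rep(seq_len(np), times = nq)
  j <- rep(seq_len(nq), each = np)
  qp_normalize(structure(list(
    num = p$num[i] * q$num[j],
    den = p$den[i] * q$den[j],
    expo = p$expo[i, , drop = FALSE] + q$expo[j, , drop = FALSE],
    vars = p$vars), class = "qpoly"))
}

# Multiply by a single monomial given as an exponent vector (fast path).
qp_mul_monomial <- function(p, expo_row) {
  if (length(p$num) == 0) return(p)
  p$expo <- sweep(p$expo, 2, expo_row, "+")
  p
}

qp_is_zero <- function(p) length(p$num) == 0

qp_equal <- function(p, q) qp_is_zero(qp_sub(p, q))

qp_degree <- function(p) if (length(p$num) == 0) -Inf else max(rowSums(p$expo))

#' Evaluate a polynomial at numeric points
#'
#' @param p a `qpoly`.
#' @param x numeric matrix with one column per variable (in `p$vars` order)
#'   and one row per evaluation point, or a named numeric vector.
#' @return numeric vector of values, one per point.
#' @keywords internal
qp_eval <- function(p, x) {
  if (is.null(dim(x))) x <- matrix(x, 1, length(x), dimnames = list(NULL, names(x)))
  if (!is.null(colnames(x))) x <- x[, p$vars, drop = FALSE]
  if (length(p$num) == 0) return(numeric(nrow(x)))
  out <- numeric(nrow(x))
  for (t in seq_along(p$num)) {
    v <- rep(p$num[t] / p$den[t], nrow(x))
    e <- p$expo[t, ]
    for (k in which(e > 0)) v <- v * x[, k]^e[k]
    out <- out + v
  }
  out
}

# Evaluate with coefficients and points in the prime field F_p.
# x: matrix of values in [0, p); returns values in [0, p).
qp_eval_mod <- function(poly, x, p) {
  if (length(poly$num) == 0) return(numeric(nrow(x)))
  coef <- mod_mul(mod_red(poly$num, p), mod_inv(mod_red(poly$den, p), p), p)
  out <- numeric(nrow(x))
  for (t in seq_along(coef)) {
    v <- rep(coef[t], nrow(x))
    e <- poly$expo[t, ]
    for (k in which(e > 0)) v <- mod_mul(v, mod_pow(x[, k], e[k], p), p)
    out <- (out + v) %% p
  }
  out
}

#' @export
format.qpoly <- function(x, ...) {
  if (length(x$num) == 0) return("0")
  terms <- vapply(seq_along(x$num), function(t) {
    coef <- if (x$den[t] == 1) sprintf("%g", x$num[t]) else
      sprintf("%g/%g", x$num[t], x$den[t])
    e <- x$expo[t, ]
    mono <- paste0(x$vars[e > 0],
                   ifelse(e[e > 0] > 1, paste0("^", e[e > 0]), ""),
                   collapse = "*")
    if (mono == "") coef else if (coef == "1") mono
    else if (coef == "-1") paste0("-", mono) else paste0(coef, "*", mono)
  }, character(1))
  paste(terms, collapse = " + ")
}

#' @export
print.qpoly <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

## ---- modular arithmetic (primes < 2^26.5 keep double products exact) ----

mod_red <- function(x, p) {
  r <- x %% p
  r[r < 0] <- r[r < 0] + p
  r
}

mod_mul <- function(a, b, p) (a * b) %% p

mod_pow <- function(a, e, p) {
  r <- rep(1, length(a))
  base <- a %% p
  while (e > 0) {
    if (e %% 2 == 1) r <- (r * base) %% p
    base <- (base * base) %% p
    e <- e %/% 2
  }
  r
}

mod_inv <- function(a, p) mod_pow(a, p - 2, p)
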