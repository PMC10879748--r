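# Ranking candidate hybridization cycles by invariant score.
#
# Every candidate partition of the taxa is scored by mapping the observed
# CF table onto its a-vector and taking the L2 norm of its signature's
# evaluated invariants; candidates are ranked by increasing score.  The
# scorer is vectorized across candidates sharing a signature, which keeps
# the full 2520-candidate scan for eight taxa to well under a second once
# the invariant sets are available.

# Batch a-vectors: rows of `A` (ncand x 3*nclasses) for all candidates in
# `cands` (which must share one signature) on the canonical CF matrix.
.batch_a_vectors <- function(tbl, cands, taxa) {
  sig <- partition_signature(cands[[1]])
  classes <- informative_classes(sig)
  class_keys <- apply(classes, 1, paste, collapse = "")
  ncand <- length(cands)
  n <- length(taxa)
  Acl <- matrix(0L, ncand, n, dimnames = list(NULL, taxa))
  for (i in seq_len(ncand))
    for (cl in 0:3) Acl[i, cands[[i]][[cl + 1]]] <- cl
  key <- do.call(paste, c(tbl[paste0("taxon", 1:4)], sep = "\r"))
  cf <- as.matrix(tbl[.cf_cols])
  subsets <- utils::combn(taxa, 4)
  sums <- matrix(0, ncand, 3L * nrow(classes))
  wt <- matrix(0, ncand, nrow(classes))
  for (s in seq_len(ncol(subsets))) {
    q <- subsets[, s]
    row <- match(paste(q, collapse = "\r"), key)
    if (is.na(row))
      stop("CF table has no row for quadruple (", paste(q, collapse = ","), ")")
    cl4 <- Acl[, q, drop = FALSE]
    ck <- paste0(rowSums(cl4 == 0L), rowSums(cl4 == 1L),
                 rowSums(cl4 == 2L), rowSums(cl4 == 3L))
    ci <- match(ck, class_keys)             # one class per candidate
    cols <- .slot_columns_vec(cl4)
    base <- 3L * (ci - 1L)
    for (slot in 1:3)
      sums[cbind(seq_len(ncand), base + slot)] <-
        sums[cbind(seq_len(ncand), base + slot)] + cf[row, cols[, slot]]
    wt[cbind(seq_len(ncand), ci)] <- wt[cbind(seq_len(ncand), ci)] + 1
  }
  sums / wt[, rep(seq_len(nrow(classes)), each = 3)]
}

# Vectorized .slot_columns: one row of slot->CF-column indices per
# candidate, for one four-taxon subset.  `cl4`: ncand x 4 clade indices.
.slot_columns_vec <- function(cl4) {
  d1 <- cl4[, 1] == cl4[, 2] | cl4[, 3] == cl4[, 4]
  d2 <- cl4[, 1] == cl4[, 3] | cl4[, 2] == cl4[, 4]
  d3 <- cl4[, 1] == cl4[, 4] | cl4[, 2] == cl4[, 3]
  dup <- ifelse(d1, 1L, ifelse(d2, 2L, ifelse(d3, 3L, 0L)))
  is1111 <- dup == 0L
  sp <- function(a, b) {                  # vectorized .split_of_pair
    lo <- pmin(a, b); hi <- pmax(a, b)
    ifelse(lo == 1L, hi, 9L - lo - hi) - 1L
  }
  s1 <- dup; s2 <- ifelse(dup == 1L, 2L, 1L)
  if (any(is1111)) {
    p0 <- max.col(cl4 == 0L, "first")
    p1 <- max.col(cl4 == 1L, "first")
    p2 <- max.col(cl4 == 2L, "first")
    s1[is1111] <- sp(p0, p1)[is1111]
    s2[is1111] <- sp(p0, p2)[is1111]
  }
  cbind(s1, s2, 6L - s1 - s2, deparse.level = 0)
}

# Squared invariant score for each row of the a-matrix `A` under `inv`.
.batch_scores <- function(A, inv) {
  total <- numeric(nrow(A))
  for (tr in inv$trivial) {
    v <- numeric(nrow(A))
    for (t in seq_along(tr$num)) {
      col <- which(tr$expo[t, ] > 0)
      v <- v + (tr$num[t] / tr$den[t]) *
        (if (length(col) == 0) 1 else A[, col])
    }
    total <- total + v^2
  }
  X <- A[, inv$reduced$a, drop = FALSE]
  for (g in inv$gens) {
    v <- numeric(nrow(A))
    for (t in seq_along(g$num)) {
      m <- rep(g$num[t] / g$den[t], nrow(A))
      e <- g$expo[t, ]
      for (k in which(e > 0)) m <- m * X[, k]^e[k]
      v <- v + m
    }
    total <- total + v^2
  }
  total
}

#' Rank all candidate hybridization cycles for a taxon set
#'
#' Scores every candidate partition of the taxa (all ordered partitions
#' into four clades of size 1 or 2) by its invariant score on the observed
#' concordance factors and returns the full ranking, smallest score first.
#' Ties are broken by the canonical text form of the partition, so
#' n1/n2-symmetric pairs appear adjacently and deterministically.
#'
#' @param tbl a CF table (canonical or not) covering every quartet of
#'   `taxa`.
#' @param taxa taxa to analyze (default: all taxa in the table); must
#'   number 5 to 8.  Use [infer_large()] beyond eight.
#' @param m how many top networks to single out (default 5, reported in
#'   `glance()` and by the command line tool).
#' @param normalized use the normalized score (L2 divided by the square
#'   root of the invariant count) instead of the raw L2 norm.
#' @param cache_dir optional invariant cache directory (see
#'   [invariant_sets()]).
#' @return A `cf_ranking`: a tibble with columns `rank`, `score`,
#'   `partition` (canonical text), `signature`, and `symmetric_rank` (the
#'   rank of the n1/n2-swapped partner), with the taxa and `m` as
#'   attributes.
#' @examples
#' \donttest{
#' p <- clade_partition(c("A", "B"), c("C", "D"), "E", "F")
#' tbl <- true_cf_table(p, network_params())
#' rank_partitions(tbl, m = 3)
#' }
#' @export
rank_partitions <- function(tbl, taxa = NULL, m = 5, normalized = FALSE,
                            cache_dir = NULL) {
  tbl <- canonicalize_cf_table(tbl, tol = NULL)
  if (is.null(taxa))
    taxa <- sort(unique(unlist(tbl[paste0("taxon", 1:4)])))
  taxa <- sort(unique(as.character(taxa)))
  cands <- enumerate_partitions(taxa)
  texts <- vapply(cands, format_partition, character(1))
  sigs <- vapply(cands, function(p) sig_label(partition_signature(p)),
                 character(1))
  scores2 <- numeric(length(cands))
  ninv <- integer(length(cands))
  for (sg in unique(sigs)) {
    idx <- which(sigs == sg)
    inv <- invariant_sets(partition_signature(as.integer(strsplit(sg, "")[[1]])),
                          cache_dir = cache_dir)
    A <- .batch_a_vectors(tbl, cands[idx], taxa)
    scores2[idx] <- .batch_scores(A, inv)
    ninv[idx] <- n_invariants(inv)
  }
  score <- sqrt(pmax(scores2, 0))
  if (normalized) score <- score / sqrt(ninv)
  ord <- order(score, texts)
  sym_text <- vapply(cands, function(p) format_partition(symmetric_partner(p)),
                     character(1))
  ranked <- tibble::tibble(
    rank = seq_along(cands),
    score = score[ord],
    partition = texts[ord],
    signature = sigs[ord])
  ranked$symmetric_rank <- match(sym_text[ord], ranked$partition)
  structure(ranked,
            class = c("cf_ranking", class(ranked)),
            taxa = taxa, m = as.integer(min(m, nrow(ranked))),
            normalized = normalized)
}

#' @export
print.cf_ranking <- function(x, ...) {
  m <- attr(x, "m")
  cat("<cf_ranking> ", nrow(x), " candidate networks over ",
      length(attr(x, "taxa")), " taxa; top ", m, ":\n", sep = "")
  print(tibble::as_tibble(x)[seq_len(m), ])
  invisible(x)
}

#' Top-m networks of a ranking
#'
#' @param ranking a `cf_ranking`.
#' @param m number of networks (default: the ranking's `m` attribute).
#' @return A tibble of the `m` best-scoring candidates.
#' @export
top_networks <- function(ranking, m = attr(ranking, "m")) {
  tibble::as_tibble(ranking)[seq_len(min(m, nrow(ranking))), ]
}

#' Rank of a partition (counting its symmetric partner)
#'
#' @param ranking a `cf_ranking`.
#' @param p a `clade_partition` (or its text form).
#' @return The best rank attained by `p` or its n1/n2-symmetric partner.
#' @export
best_rank <- function(ranking, p) {
  if (inherits(p, "clade_partition")) {
    t1 <- format_partition(p)
    t2 <- format_partition(symmetric_partner(p))
  } else {
    t1 <- p
    t2 <- format_partition(symmetric_partner(parse_partition(p)))
  }
  min(ranking$rank[ranking$partition %in% c(t1, t2)])
}

#' Infer a hybridization cycle for more than eight taxa
#'
#' Invariant sets exist for up to eight taxa, so larger taxon sets are
#' handled by scoring every candidate on every eight-taxon subset, pooling
#' all candidates into one global ranking, taking the best eight-taxon
#' network N8*, and then placing each remaining taxon according to its
#' clade in the highest-ranked candidate that (a) contains it and (b)
#' assigns every taxon shared with N8* to the same clade as N8*.
#'
#' @param tbl a CF table covering every quartet of `taxa`.
#' @param taxa more than eight taxon labels (default: all in the table).
#' @param m top networks to report per the pooled ranking.
#' @param cache_dir optional invariant cache directory.
#' @return A list with `partition` (a `clade_partition` over all taxa;
#'   unplaceable taxa are reported in `unplaced` instead), `ranking` (the
#'   pooled `cf_ranking` across subsets), and `placements` (a tibble
#'   logging, for each added taxon, the rank of the candidate that placed
#'   it and the clade chosen).
#' @export
infer_large <- function(tbl, taxa = NULL, m = 5, cache_dir = NULL) {
  tbl <- canonicalize_cf_table(tbl, tol = NULL)
  if (is.null(taxa))
    taxa <- sort(unique(unlist(tbl[paste0("taxon", 1:4)])))
  taxa <- sort(unique(as.character(taxa)))
  if (length(taxa) <= 8)
    stop("infer_large() is for more than eight taxa; use rank_partitions()")
  subsets <- utils::combn(taxa, 8)
  pieces <- vector("list", ncol(subsets))
  for (s in seq_len(ncol(subsets))) {
    r <- rank_partitions(tbl, taxa = subsets[, s], m = m,
                         cache_dir = cache_dir)
    pieces[[s]] <- tibble::as_tibble(r)[c("score", "partition", "signature")]
  }
  pooled <- dplyr::arrange(dplyr::bind_rows(pieces), score, partition)
  pooled$rank <- seq_len(nrow(pooled))
  best <- parse_partition(pooled$partition[1])
  best_taxa <- sort(unlist(best))
  clade_of_best <- integer(0)
  for (cl in 0:3) clade_of_best[best[[cl + 1]]] <- cl
  missing_taxa <- setdiff(taxa, best_taxa)
  placements <- list()
  clades <- lapply(best, identity)
  unplaced <- character(0)
  for (tx in missing_taxa) {
    placed <- FALSE
    for (r in seq_len(nrow(pooled))) {
      q <- parse_partition(pooled$partition[r])
      q_taxa <- unlist(q)
      if (!(tx %in% q_taxa)) next
      clade_of_q <- integer(0)
      for (cl in 0:3) clade_of_q[q[[cl + 1]]] <- cl
      shared <- intersect(q_taxa, best_taxa)
      if (!all(clade_of_q[shared] == clade_of_best[shared])) next
      cl <- clade_of_q[[tx]]
      clades[[cl + 1]] <- c(clades[[cl + 1]], tx)
      placements[[length(placements) + 1L]] <- tibble::tibble(
        taxon = tx, clade = cl, via_rank = r,
        via_partition = pooled$partition[r])
      placed <- TRUE
      break
    }
    if (!placed) {
      unplaced <- c(unplaced, tx)
      warning("taxon '", tx, "' could not be placed consistently with the ",
              "best eight-taxon network")
    }
  }
  ranking <- structure(pooled[c("rank", "score", "partition", "signature")],
                       class = c("cf_ranking", class(pooled)),
                       taxa = taxa, m = as.integer(min(m, nrow(pooled))),
                       normalized = FALSE)
  list(partition = clade_partition(clades[[1]], clades[[2]], clades[[3]],
                                   clades[[4]]),
       unplaced = unplaced,
       ranking = ranking,
       placements = if (length(placements)) dplyr::bind_rows(placements)
       else tibble::tibble(taxon = character(0), clade = integer(0),
                           via_rank = integer(0),
                           via_partition = character(0)))
}
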