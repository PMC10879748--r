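# Concordance-factor tables and their mapping onto candidate networks.
#
# A CF table has one row per four-taxon subset: the four labels plus the
# three split frequencies CF12_34, CF13_24, CF14_23, read relative to the
# order of the labels in that row (CF12_34 is the frequency of the split
# grouping taxon1 with taxon2).  Tables are canonicalized so taxa are
# sorted within each row, with the CF columns permuted accordingly.

.cf_cols <- c("CF12_34", "CF13_24", "CF14_23")

#' Canonicalize a CF table
#'
#' Sorts the four taxa of every row and permutes the CF columns to match,
#' so that equivalent rows become identical.
#'
#' @param tbl a data frame with columns `taxon1..taxon4` and
#'   `CF12_34, CF13_24, CF14_23` (optionally `ngenes`).
#' @param tol tolerance for the sum-to-one check; use `NULL` to skip it
#'   (e.g. for Gaussian-perturbed tables).
#' @return A tibble in canonical form, sorted by taxon quadruple.
#' @export
canonicalize_cf_table <- function(tbl, tol = 1e-6) {
  tbl <- tibble::as_tibble(tbl)
  need <- c(paste0("taxon", 1:4), .cf_cols)
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0)
    stop("CF table is missing column(s): ", paste(miss, collapse = ", "))
  for (cc in .cf_cols)
    if (!is.numeric(tbl[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(tbl[[cc]]))))[1]
      stop("non-numeric value in ", cc, " at row ", bad)
    }
  out <- tbl
  for (r in seq_len(nrow(tbl))) {
    tx <- as.character(unlist(tbl[r, paste0("taxon", 1:4)]))
    if (anyDuplicated(tx))
      stop("row ", r, ": duplicated taxon within the quadruple (",
           paste(tx, collapse = ","), ")")
    ord <- order(tx)
    s <- tx[ord]
    cf <- as.numeric(unlist(tbl[r, .cf_cols]))
    # the canonical split k pairs s[1] with s[k+1]; find the original
    # column that groups the same two taxa
    newcf <- vapply(2:4, function(k) {
      cf[.split_of_pair(match(s[1], tx), match(s[k], tx))]
    }, numeric(1))
    out[r, paste0("taxon", 1:4)] <- as.list(s)
    out[r, .cf_cols] <- as.list(newcf)
  }
  key <- do.call(paste, c(out[paste0("taxon", 1:4)], sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate quadruple at row ", which(duplicated(key))[1], ": ",
         gsub("\r", ",", key[duplicated(key)][1]))
  if (!is.null(tol)) {
    sums <- out$CF12_34 + out$CF13_24 + out$CF14_23
    bad <- which(abs(sums - 1) > tol)
    if (length(bad) > 0)
      stop("CF triple at row ", bad[1], " sums to ", format(sums[bad[1]]),
           " (tolerance ", tol, "); pass tol = NULL for perturbed tables")
  }
  out[order(key), ]
}

#' Read a CF table from CSV
#'
#' @param path CSV file with header
#'   `taxon1,taxon2,taxon3,taxon4,CF12_34,CF13_24,CF14_23` (an optional
#'   `ngenes` column is kept).
#' @param tol sum-to-one tolerance passed to [canonicalize_cf_table()];
#'   `NULL` disables the check.
#' @return A canonical CF tibble.
#' @export
read_cf_table <- function(path, tol = 1e-6) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(taxon1 = "character",
                                        taxon2 = "character",
                                        taxon3 = "character",
                                        taxon4 = "character"))
  canonicalize_cf_table(raw, tol = tol)
}

#' Write a CF table to CSV
#'
#' @param tbl a CF table (canonicalized first).
#' @param path output file.
#' @param tol passed to [canonicalize_cf_table()].
#' @return `path`, invisibly.
#' @export
write_cf_table <- function(tbl, path, tol = NULL) {
  tbl <- canonicalize_cf_table(tbl, tol = tol)
  utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Estimate concordance factors from gene trees
#'
#' Counts, for every four-taxon subset, the frequency of each quartet split
#' among the gene trees that contain all four taxa and resolve the quartet.
#' Trees may be non-binary (unresolved quartets are skipped) and may carry
#' multiple individuals per taxon once `mapping` is supplied: each choice
#' of one individual per taxon counts as a fractional observation.
#'
#' @param trees character vector of Newick strings (one tree per element),
#'   or a list of `phylo` objects / a `multiPhylo`.
#' @param taxa taxa to tabulate (default: all labels seen).
#' @param mapping optional data frame with columns `individual`, `taxon`
#'   renaming tip labels before counting.
#' @return A canonical CF tibble with an `ngenes` column giving the number
#'   of informative observations per quartet.  Quartets with no informative
#'   tree are omitted with a warning.
#' @examples
#' trees <- c("((A,B),(C,D));", "((A,B),(C,D));", "((A,C),(B,D));")
#' cfs_from_gene_trees(trees)
#' @export
cfs_from_gene_trees <- function(trees, taxa = NULL, mapping = NULL) {
  if (is.character(trees))
    trees <- ape::read.tree(text = paste(trees, collapse = "\n"))
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- lapply(trees, function(tr) {
    if (!is.null(mapping)) {
      m <- match(tr$tip.label, mapping$individual)
      tr$tip.label[!is.na(m)] <- mapping$taxon[m[!is.na(m)]]
    }
    tr$edge.length <- rep(1, nrow(tr$edge))   # topological distances only
    tr
  })
  if (is.null(taxa)) taxa <- sort(unique(unlist(lapply(trees, `[[`, "tip.label"))))
  taxa <- sort(unique(as.character(taxa)))
  if (length(taxa) < 4) stop("need at least four taxa to form quartets")
  subsets <- utils::combn(taxa, 4)
  counts <- matrix(0, ncol(subsets), 3)
  denom <- numeric(ncol(subsets))
  for (tr in trees) {
    D <- ape::cophenetic.phylo(tr)
    tips <- rownames(D)
    reps <- split(seq_along(tips), tips)
    for (s in seq_len(ncol(subsets))) {
      q <- subsets[, s]
      if (!all(q %in% names(reps))) next
      combos <- expand.grid(reps[q], KEEP.OUT.ATTRS = FALSE)
      w <- 1 / nrow(combos)
      for (ci in seq_len(nrow(combos))) {
        ii <- as.integer(combos[ci, ])
        d12 <- D[ii[1], ii[2]] + D[ii[3], ii[4]]
        d13 <- D[ii[1], ii[3]] + D[ii[2], ii[4]]
        d14 <- D[ii[1], ii[4]] + D[ii[2], ii[3]]
        dd <- c(d12, d13, d14)
        mn <- which(dd == min(dd))
        if (length(mn) == 1) {              # resolved quartet
          counts[s, mn] <- counts[s, mn] + w
          denom[s] <- denom[s] + w
        }
      }
    }
  }
  keep <- denom > 0
  if (any(!keep))
    warning(sum(!keep), " quartet(s) had no informative gene tree and were",
            " omitted, e.g. (", paste(subsets[, which(!keep)[1]],
                                      collapse = ","), ")")
  out <- tibble::tibble(
    taxon1 = subsets[1, keep], taxon2 = subsets[2, keep],
    taxon3 = subsets[3, keep], taxon4 = subsets[4, keep],
    CF12_34 = counts[keep, 1] / denom[keep],
    CF13_24 = counts[keep, 2] / denom[keep],
    CF14_23 = counts[keep, 3] / denom[keep],
    ngenes = denom[keep])
  canonicalize_cf_table(out, tol = NULL)
}

# Slot columns of a canonical CF row for a given candidate partition:
# which of the three CF columns is the class-predicted split (slot 1) and
# which are slots 2 and 3.  `cl4` is the clade index (0..3) of the four
# sorted taxa of the row.
.slot_columns <- function(cl4) {
  dup <- NA_integer_
  if (cl4[1] == cl4[2]) dup <- 1L
  else if (cl4[1] == cl4[3]) dup <- 2L
  else if (cl4[1] == cl4[4]) dup <- 3L
  else if (cl4[2] == cl4[3]) dup <- 3L   # pair {2,3} -> split 14|23
  else if (cl4[2] == cl4[4]) dup <- 2L   # pair {2,4} -> split 13|24
  else if (cl4[3] == cl4[4]) dup <- 1L   # pair {3,4} -> split 12|34
  if (!is.na(dup)) {
    rest <- setdiff(1:3, dup)            # remaining minors in column order
    return(c(dup, rest))
  }
  # class (1,1,1,1): slots fixed by clade indices
  p0 <- which(cl4 == 0L); p1 <- which(cl4 == 1L); p2 <- which(cl4 == 2L)
  s1 <- .split_of_pair(p0, p1)
  s2 <- .split_of_pair(p0, p2)
  c(s1, s2, setdiff(1:3, c(s1, s2)))
}

#' Map observed concordance factors onto a candidate's a-vector
#'
#' For each informative class of the candidate partition's signature,
#' enumerates all realizations (four-taxon subsets whose per-clade counts
#' match the class), assigns each realization's observed CFs to slots (slot
#' 1 is the class-predicted split; the minor slots follow the canonical
#' column order of the sorted row), and averages per slot across
#' realizations.
#'
#' @param tbl a canonical CF table covering all quartets of the
#'   partition's taxa.
#' @param p a `clade_partition`.
#' @return Named numeric a-vector in the canonical order of
#'   `partition_signature(p)`.
#' @export
map_to_a_vector <- function(tbl, p) {
  stopifnot(inherits(p, "clade_partition"))
  sig <- partition_signature(p)
  sys_classes <- informative_classes(sig)
  class_keys <- apply(sys_classes, 1, paste, collapse = "")
  taxa <- sort(unlist(p))
  clade_of <- integer(0)
  for (cl in 0:3) clade_of[p[[cl + 1]]] <- cl
  key <- do.call(paste, c(tbl[paste0("taxon", 1:4)], sep = "\r"))
  cf <- as.matrix(tbl[.cf_cols])
  subsets <- utils::combn(taxa, 4)
  sums <- matrix(0, length(class_keys), 3)
  wt <- numeric(length(class_keys))
  for (s in seq_len(ncol(subsets))) {
    q <- subsets[, s]
    row <- match(paste(q, collapse = "\r"), key)
    if (is.na(row))
      stop("CF table has no row for quadruple (", paste(q, collapse = ","),
           ")")
    cl4 <- clade_of[q]
    ck <- paste(tabulate(cl4 + 1L, 4L), collapse = "")
    ci <- match(ck, class_keys)
    if (is.na(ci)) next                     # uninformative (3+ from a clade)
    cols <- .slot_columns(cl4)
    sums[ci, ] <- sums[ci, ] + cf[row, cols]
    wt[ci] <- wt[ci] + 1
  }
  a <- as.vector(t(sums / wt))
  names(a) <- paste0("a", seq_along(a))
  a
}
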