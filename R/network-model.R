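# Candidate networks as ordered clade partitions.
#
# A four-node hybridization cycle h-v1-v3-v2-h on a level-1 semi-directed
# network partitions the taxa into four clades: the hybrid clade (index 0,
# below the hybrid node h), the two clades attached to the hybrid parents
# (indices 1 and 2, at cycle nodes v1 and v2), and the clade attached to the
# node opposite the hybrid (index 3, at v3).  A candidate network is fully
# specified by this ordered partition; within-clade topology is never
# resolved by the method.

#' Create a clade partition
#'
#' Builds a validated ordered partition of taxa into the four clades of a
#' four-node hybridization cycle: `clade0` is the hybrid clade, `clade1` and
#' `clade2` attach to the two hybrid parents, and `clade3` attaches to the
#' cycle node opposite the hybrid.
#'
#' @param clade0,clade1,clade2,clade3 character vectors of taxon labels;
#'   each must be nonempty and the four must be pairwise disjoint.
#' @return An object of class `clade_partition`: a list of four sorted
#'   character vectors with the signature (clade sizes) as an attribute.
#' @examples
#' p <- clade_partition(c("A", "B"), c("C", "D"), c("E", "F"), c("G", "H"))
#' partition_signature(p)
#' @export
clade_partition <- function(clade0, clade1, clade2, clade3) {
  clades <- list(clade0, clade1, clade2, clade3)
  for (i in seq_along(clades)) {
    cl <- clades[[i]]
    if (length(cl) == 0 || !is.character(cl) || any(!nzchar(cl)) || anyNA(cl))
      stop("clade ", i - 1, " must be a nonempty character vector of taxon labels",
           call. = FALSE)
    if (anyDuplicated(cl))
      stop("duplicate taxon '", cl[duplicated(cl)][1], "' within clade ", i - 1,
           call. = FALSE)
    clades[[i]] <- sort(cl)
  }
  all_taxa <- unlist(clades)
  if (anyDuplicated(all_taxa)) {
    dup <- all_taxa[duplicated(all_taxa)][1]
    stop("taxon '", dup, "' appears in more than one clade", call. = FALSE)
  }
  structure(clades,
            names = paste0("n", 0:3),
            signature = lengths(clades),
            class = "clade_partition")
}

#' Signature of a clade partition
#'
#' @param p a `clade_partition`, or an integer 4-vector of clade sizes.
#' @return Integer 4-vector `(n0, n1, n2, n3)` of clade sizes.
#' @export
partition_signature <- function(p) {
  if (inherits(p, "clade_partition")) return(as.integer(attr(p, "signature")))
  sig <- as.integer(p)
  if (length(sig) != 4 || any(sig < 1)) stop("a signature is four positive clade sizes")
  sig
}

# A signature is supported by the invariant machinery when every clade
# contributes at most two taxa and the network has 5..8 taxa in total.
is_supported_signature <- function(sig) {
  sig <- as.integer(sig)
  length(sig) == 4 && all(sig >= 1) && all(sig <= 2) &&
    sum(sig) >= 5 && sum(sig) <= 8
}

assert_supported_signature <- function(sig) {
  if (!is_supported_signature(sig))
    stop("unsupported signature (", paste(sig, collapse = ","),
         "): clade sizes must be 1 or 2 with 5-8 taxa in total", call. = FALSE)
  as.integer(sig)
}

#' All supported signatures
#'
#' @return A list of the 15 integer 4-vectors with entries in \{1, 2\} and
#'   total 5 to 8: the signatures for which invariant sets are available.
#' @export
supported_signatures <- function() {
  grid <- as.matrix(expand.grid(n3 = 1:2, n2 = 1:2, n1 = 1:2, n0 = 1:2))
  grid <- grid[, 4:1, drop = FALSE]
  grid <- grid[rowSums(grid) >= 5, , drop = FALSE]
  grid <- grid[order(apply(grid, 1, paste, collapse = "")), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

sig_label <- function(sig) paste(sig, collapse = "")

#' Canonical text form of a partition
#'
#' Formats a partition as `"n0=A,B;n1=C,D;n2=E,F;n3=G,H"` (taxa sorted
#' within clades).  This is the serialization used in ranking tables and on
#' the command line; [parse_partition()] inverts it.
#'
#' @param p a `clade_partition`.
#' @return A single string.
#' @export
format_partition <- function(p) {
  stopifnot(inherits(p, "clade_partition"))
  paste0("n", 0:3, "=", vapply(p, paste, character(1), collapse = ","),
         collapse = ";")
}

#' @export
format.clade_partition <- function(x, ...) format_partition(x)

#' @export
print.clade_partition <- function(x, ...) {
  cat("<clade_partition> signature", sig_label(partition_signature(x)), "\n")
  cat(" ", format_partition(x), "\n")
  invisible(x)
}

#' Parse the text form of a partition
#'
#' @param text a string like `"n0=A,B;n1=C,D;n2=E,F;n3=G,H"`.
#' @return A `clade_partition`.
#' @export
parse_partition <- function(text) {
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  if (length(parts) != 4) stop("expected four ';'-separated clades in '", text, "'")
  labs <- sub("=.*$", "", parts)
  if (!identical(labs, paste0("n", 0:3)))
    stop("clades must be given in order n0=...;n1=...;n2=...;n3=...")
  clades <- lapply(parts, function(s) strsplit(sub("^n[0-3]=", "", s), ",")[[1]])
  clade_partition(clades[[1]], clades[[2]], clades[[3]], clades[[4]])
}

#' Enumerate all candidate partitions of a taxon set
#'
#' Lists every ordered partition of the taxa into four nonempty clades whose
#' signature has all entries in \{1, 2\} — the candidate space searched by
#' the ranking step.  Both members of each n1/n2-symmetric pair are present,
#' and the order is deterministic (sorted by canonical text form).
#'
#' @param taxa character vector of 5 to 8 distinct taxon labels.
#' @return A list of `clade_partition` objects.
#' @examples
#' length(enumerate_partitions(LETTERS[1:6]))  # 1080
#' @export
enumerate_partitions <- function(taxa) {
  taxa <- sort(unique(as.character(taxa)))
  n <- length(taxa)
  if (n < 5 || n > 8)
    stop("candidate enumeration supports 5-8 taxa (got ", n,
         "); use infer_large() for more", call. = FALSE)
  sigs <- Filter(function(s) sum(s) == n, supported_signatures())
  out <- list()
  for (sig in sigs) {
    # choose clade0, then clade1, clade2 from the remainder; clade3 is the rest
    c0s <- utils::combn(taxa, sig[1], simplify = FALSE)
    for (c0 in c0s) {
      rest1 <- setdiff(taxa, c0)
      c1s <- utils::combn(rest1, sig[2], simplify = FALSE)
      for (c1 in c1s) {
        rest2 <- setdiff(rest1, c1)
        c2s <- utils::combn(rest2, sig[3], simplify = FALSE)
        for (c2 in c2s) {
          c3 <- setdiff(rest2, c2)
          out[[length(out) + 1L]] <- clade_partition(c0, c1, c2, c3)
        }
      }
    }
  }
  out[order(vapply(out, format_partition, character(1)))]
}

#' The n1/n2-symmetric partner of a partition
#'
#' Swaps the two clades attached to the hybrid parents.  Both members of a
#' symmetric pair describe the same unordered attachment of clades to the
#' cycle, and their invariant scores agree to machine precision; the method
#' cannot distinguish them without estimating the inheritance probability.
#'
#' @param p a `clade_partition`.
#' @return A `clade_partition` with clades 1 and 2 exchanged.
#' @export
symmetric_partner <- function(p) {
  stopifnot(inherits(p, "clade_partition"))
  clade_partition(p[[1]], p[[3]], p[[2]], p[[4]])
}

#' Extended Newick form of a partition
#'
#' Writes the four-node cycle as an extended Newick string with one hybrid
#' node tagged `#H1` (appearing twice).  Clades with two or more taxa are
#' written as polytomies since within-clade topology is not inferred; branch
#' lengths and the inheritance probability are omitted.  Output is
#' deterministic (taxa sorted within clades).
#'
#' @param p a `clade_partition`.
#' @return A single eNewick string, parseable e.g. by [ape::read.evonet()].
#' @examples
#' as_enewick(clade_partition("A", "B", "C", c("D", "E")))
#' @export
as_enewick <- function(p) {
  stopifnot(inherits(p, "clade_partition"))
  wrap <- function(cl) if (length(cl) == 1) cl else
    paste0("(", paste(cl, collapse = ","), ")")
  hyb <- paste0("(", paste(p[[1]], collapse = ","), ")#H1")
  paste0("((", wrap(p[[2]]), ",", hyb, "),(", wrap(p[[3]]), ",#H1),",
         wrap(p[[4]]), ");")
}
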