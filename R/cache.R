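# Persisting invariant sets.
#
# One JSON file per signature.  The schema stores the signature, the
# provenance tag, the reduced-coordinate map, and the nontrivial generators
# as exact term lists (integer numerators/denominators plus exponent rows
# over the reduced coordinates), together with a checksum over the
# serialized numbers.  Trivial invariants are reconstructed on load rather
# than stored.  Loading re-validates the set by checking that every
# invariant vanishes on freshly generated model concordance factors.

.inv_checksum <- function(gens) {
  # order-sensitive polynomial hash over all numbers in the generator list
  acc <- 0
  p <- 2147483629
  feed <- function(x) {
    for (v in x) acc <<- (acc * 31 + (v %% p)) %% p
  }
  for (g in gens) {
    feed(g$num); feed(g$den); feed(as.numeric(t(g$expo)))
  }
  acc
}

#' Store an invariant set as JSON
#'
#' @param inv an `invariant_set`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
store_invariants <- function(inv, path) {
  stopifnot(inherits(inv, "invariant_set"))
  obj <- list(
    format = "quartetinv-invariants-1",
    signature = inv$signature,
    provenance = inv$provenance,
    reduced_a = inv$reduced$a,
    n_vars = nrow(inv$reduced),
    gens = lapply(inv$gens, function(g)
      list(num = g$num, den = g$den, expo = as.vector(t(g$expo)))),
    checksum = .inv_checksum(inv$gens))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an invariant set from JSON
#'
#' Verifies the stored checksum and re-validates the set by evaluating
#' every invariant on model concordance factors at `n_check` random
#' parameter draws; corrupt or tampered files fail to load.
#'
#' @param path file written by [store_invariants()].
#' @param n_check number of validation draws.
#' @param tol vanishing tolerance for validation.
#' @return An `invariant_set`.
#' @export
load_invariants <- function(path, n_check = 10, tol = 1e-8) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "quartetinv-invariants-1"))
    stop("not a quartetinv invariant cache: ", path)
  sig <- assert_supported_signature(as.integer(obj$signature))
  v <- as.integer(obj$n_vars)
  gens <- lapply(seq_along(obj$gens$num), function(i) list(
    num = as.numeric(obj$gens$num[[i]]),
    den = as.numeric(obj$gens$den[[i]]),
    expo = matrix(as.integer(obj$gens$expo[[i]]), ncol = v, byrow = TRUE)))
  if (.inv_checksum(gens) != as.numeric(obj$checksum))
    stop("invariant cache checksum mismatch (file corrupt or edited): ", path)
  rv <- reduced_vars(sig)
  if (!identical(as.integer(obj$reduced_a), rv$a))
    stop("invariant cache reduced-coordinate map does not match ", path)
  inv <- .new_invariant_set(sig, rv, gens, provenance = obj$provenance)
  worst <- 0
  draws <- withr_seed(5150 + sum(sig * c(1000, 100, 10, 1)), function()
    random_params(n_check))
  for (pp in draws)
    worst <- max(worst, max(abs(invariant_values(inv, evaluate_cfs(sig, pp)))))
  if (worst > tol)
    stop("loaded invariants fail model validation (max residual ",
         format(worst), "): ", path)
  inv
}

#' Get the invariant set of a signature
#'
#' Front door used by the ranking code: returns the memoized invariant set
#' for a signature, deriving it on first use (or loading it from
#' `cache_dir` when a stored copy exists there, and storing a freshly
#' derived set back into `cache_dir` when given).
#'
#' @param sig a supported signature.
#' @param cache_dir optional directory of JSON caches written by
#'   [store_invariants()].
#' @return An `invariant_set`.
#' @export
invariant_sets <- function(sig, cache_dir = NULL) {
  sig <- assert_supported_signature(partition_signature(sig))
  if (!is.null(cache_dir)) {
    f <- file.path(cache_dir, paste0("invariants-", sig_label(sig), ".json"))
    if (file.exists(f)) return(load_invariants(f))
    inv <- derive_invariants(sig)
    dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
    store_invariants(inv, f)
    return(inv)
  }
  derive_invariants(sig)
}
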