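# Per-session memoization of symbolic objects (CF polynomials, invariant
# sets).  Everything cached here is deterministic, so caching is purely a
# speed concern.
.qi_cache <- new.env(parent = emptyenv())

qi_cache_clear <- function() {
  rm(list = ls(.qi_cache), envir = .qi_cache)
  invisible(NULL)
}
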