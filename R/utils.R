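# Run an expression under a temporary RNG state so package functions are
# reproducible from explicit seeds without clobbering the caller's stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive independent sub-seeds (corpus, model init, batch order, ...) from one
# master seed, kept inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435761 + 97 * k) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
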