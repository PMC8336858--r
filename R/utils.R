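# internal helpers

#' @importFrom stats runif setNames
NULL

# stable 31-bit polynomial hash of a string; used to derive per-reaction RNG
# substreams so adding a reaction does not perturb other reactions' draws
stableHash <- function(s) {
  codes <- utf8ToInt(s)
  h <- 0
  for (ch in codes) h <- (h * 131 + ch) %% 2147483647
  as.integer(h)
}

# derive a child seed below 2^31 from a root seed and a string label
childSeed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 + stableHash(label)) %% 2147483647)
}

# run expr with a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
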