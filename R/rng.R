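#' Derive a reproducible child seed from a master seed and a key
#'
#' Simulation components each draw randomness from their own stream so that,
#' e.g., adding an annotator never perturbs the phantoms or the other
#' annotators. Streams are identified by a string key (typically
#' "case/annotator/pass") hashed together with the master seed into a 31-bit
#' integer seed.
#'
#' @param seed master seed (integer).
#' @param ... key components (coerced to character and joined with "/").
#' @return an integer in `[0, 2^31 - 2]`, suitable for `set.seed()`.
#' @export
child_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  bytes <- utf8ToInt(key)
  # 31-bit multiplicative hash; products stay below 2^53 so doubles are exact
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so library code never clobbers the
#' caller's stream.
#'
#' @param seed seed for the local stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
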